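#' Parameters of a synthetic whole-mount skin field
#'
#' Bundles the imaging geometry and signal model of one simulated two-channel
#' whole-mount field. Defaults emulate a typical UVB-irradiated dorsal-skin
#' acquisition: about 320 autofluorescent hair follicles per field (the red
#' channel), sparse nuclear H2B-GFP point signals in the green channel, and a
#' fixed fraction of the red signal bleeding into green.
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param n_follicles number of hair follicles placed in the field.
#' @param follicle_radius_px length-2 range (min, max) of follicle radii in px.
#' @param follicle_peak_intensity length-2 range of follicle peak intensities
#'   (arbitrary units on the same scale as `bg_level`).
#' @param mcsc_rate expected number of epidermal melanocytes per follicle; the
#'   per-field melanocyte count is drawn as
#'   Poisson(`n_follicles * mcsc_rate`).
#' @param spot_sigma_px Gaussian point-spread standard deviation of one
#'   H2B-GFP nucleus, in px.
#' @param spot_peak_intensity length-2 range of spot peak intensities.
#' @param bleed_alpha fraction of the noise-free red channel leaking into the
#'   green channel, in `[0, 1)`.
#' @param bg_level constant background level added to both channels.
#' @param noise_sd standard deviation of additive Gaussian detector noise.
#' @param seed integer seed; every stochastic draw of the generator is
#'   governed by it.
#'
#' @return An object of class `FieldParams` (a validated named list).
#' @examples
#' p <- field_params(width_px = 512, height_px = 512, n_follicles = 20, seed = 7)
#' p$n_follicles
#' @export
field_params <- function(width_px = 2048L,
                         height_px = 2048L,
                         pixel_size_um = 1.0,
                         n_follicles = 320L,
                         follicle_radius_px = c(12, 20),
                         follicle_peak_intensity = c(500, 1000),
                         mcsc_rate = 0.05,
                         spot_sigma_px = 2,
                         spot_peak_intensity = c(800, 1200),
                         bleed_alpha = 0.30,
                         bg_level = 100,
                         noise_sd = 10,
                         seed = 1L) {
  assert_scalar_num(width_px, "width_px", lower = 16)
  assert_scalar_num(height_px, "height_px", lower = 16)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_follicles, "n_follicles", lower = 0)
  assert_scalar_num(mcsc_rate, "mcsc_rate", lower = 0)
  assert_scalar_num(spot_sigma_px, "spot_sigma_px", lower = 0, strict_lower = TRUE)
  assert_scalar_num(bleed_alpha, "bleed_alpha", lower = 0, upper = 1 - 1e-12)
  assert_scalar_num(bg_level, "bg_level", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(seed, "seed")
  for (nm in c("follicle_radius_px", "follicle_peak_intensity",
               "spot_peak_intensity")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || any(v <= 0) || v[1] > v[2])
      stop_mcsc("mcsc_validation_error",
                sprintf("'%s' must be an increasing positive (min, max) pair", nm))
  }
  if (n_follicles * pi * max(follicle_radius_px)^2 >= 0.5 * width_px * height_px)
    stop_mcsc("mcsc_validation_error",
              "follicle placement infeasible: requested follicle area exceeds half the field")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    n_follicles = as.integer(n_follicles),
    follicle_radius_px = as.numeric(follicle_radius_px),
    follicle_peak_intensity = as.numeric(follicle_peak_intensity),
    mcsc_rate = mcsc_rate,
    spot_sigma_px = spot_sigma_px,
    spot_peak_intensity = as.numeric(spot_peak_intensity),
    bleed_alpha = bleed_alpha,
    bg_level = bg_level, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "FieldParams")
}

#' @export
print.FieldParams <- function(x, ...) {
  cat(sprintf("FieldParams: %dx%d px (%.2f um/px), %d follicles, mcsc_rate %.3g, bleed %.2f, seed %d\n",
              x$width_px, x$height_px, x$pixel_size_um, x$n_follicles,
              x$mcsc_rate, x$bleed_alpha, x$seed))
  invisible(x)
}

#' Detection configuration for whole-mount and section quantification
#'
#' All tunable thresholds of the quantification pipeline in one nested list.
#' Every parameter has a documented default; pass overrides as nested lists,
#' e.g. `quant_config(spot = list(threshold_k = 4))`.
#'
#' @param follicle follicle-detection settings: `smooth_sigma` (Gaussian
#'   smoothing sd, px), `threshold` ("otsu", "quantile" or "absolute"),
#'   `threshold_level` (quantile or absolute level when not Otsu; NA = unset),
#'   `open_radius` (binary-opening radius, px), `min_area`/`max_area`
#'   (component area gate, px).
#' @param bleed bleed-estimation settings: `method` ("theil_sen" or "lsq"),
#'   `max_points` (pixel subsample for the robust fit), `dilate_px`
#'   (follicle-mask dilation), `min_pixels` (minimum mask size).
#' @param spot spot-detection settings: `sigmas` (Laplacian-of-Gaussian scale
#'   set, px), `threshold_k` (intensity threshold in robust background MADs),
#'   `threshold_abs` (absolute intensity threshold overriding `threshold_k`;
#'   NA = unset),
#'   `min_separation_px` (non-maximum-suppression radius).
#' @param cell cell/section settings: `threshold` and `threshold_level` as for
#'   follicles, `min_area`/`max_area` cell-size gate (px).
#' @param max_alpha bleed coefficients above this raise a
#'   `suspect_channel_order` flag (physical bleed-through is well below 1).
#'
#' @return Object of class `QuantConfig`.
#' @export
quant_config <- function(follicle = list(), bleed = list(), spot = list(),
                         cell = list(), max_alpha = 1) {
  cfg <- list(
    follicle = modifyList(list(
      smooth_sigma = 4, threshold = "otsu", threshold_level = NA_real_,
      open_radius = 2L, min_area = 100, max_area = 8000
    ), follicle),
    bleed = modifyList(list(
      method = "theil_sen", max_points = 1500L, dilate_px = 3L,
      min_pixels = 200L
    ), bleed),
    spot = modifyList(list(
      sigmas = c(1.5, 2, 3), threshold_k = 5, threshold_abs = NA_real_,
      min_separation_px = 6
    ), spot),
    cell = modifyList(list(
      threshold = "otsu", threshold_level = NA_real_,
      min_area = 20, max_area = 2000
    ), cell),
    max_alpha = max_alpha
  )
  structure(cfg, class = "QuantConfig")
}

as_quant_config <- function(config) {
  if (is.null(config)) return(quant_config())
  if (inherits(config, "QuantConfig")) return(config)
  if (is.list(config))
    return(do.call(quant_config, config[intersect(names(config),
      c("follicle", "bleed", "spot", "cell", "max_alpha"))]))
  stop_mcsc("mcsc_validation_error", "invalid detection config")
}
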