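#' Simulate one two-channel whole-mount skin field with ground truth
#'
#' Builds the red channel as constant background plus radially decaying
#' follicle autofluorescence blobs at jittered-hexagonal-grid centres
#' (minimum centre separation 2.5 x the maximum follicle radius), and the
#' green channel as background plus `bleed_alpha` times the noise-free red
#' plus isotropic Gaussian H2B-GFP nuclear spots at uniformly placed
#' positions; the per-field spot count is Poisson(`n_follicles * mcsc_rate`).
#' Independent additive Gaussian noise is applied to each channel last and
#' intensities are clipped at zero. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params a [field_params()] object.
#' @param field_id,mouse_id identifiers stored in the returned field.
#'
#' @return A list with elements `field` (class `TwoChannelField`: matrices
#'   `green` and `red`, `pixel_size_um`, `field_id`, `mouse_id`) and `truth`
#'   (class `SyntheticTruth`: follicle centres/radii/peaks, melanocyte
#'   positions and peaks, `bleed_alpha`, the `params` used). Coordinates are
#'   0-based with x = column, y = row.
#' @examples
#' sim <- generate_wholemount(field_params(width_px = 256, height_px = 256,
#'                                         n_follicles = 5, seed = 3))
#' nrow(sim$truth$follicle_centers)
#' @export
generate_wholemount <- function(params, field_id = "field01",
                                mouse_id = "mouse01") {
  if (!inherits(params, "FieldParams"))
    stop_mcsc("mcsc_validation_error", "'params' must come from field_params()")
  W <- params$width_px; H <- params$height_px
  with_seed(params$seed, {
    centers <- place_follicles(params)
    n <- nrow(centers)
    radii <- runif(n, params$follicle_radius_px[1], params$follicle_radius_px[2])
    peaks <- runif(n, params$follicle_peak_intensity[1],
                   params$follicle_peak_intensity[2])
    red_clean <- params$bg_level +
      .render_blobs(H, W, centers$x, centers$y, radii, peaks)

    n_spots <- rpois(1, params$n_follicles * params$mcsc_rate)
    spots <- data.frame(
      x = runif(n_spots, 0, W - 1),
      y = runif(n_spots, 0, H - 1)
    )
    spot_peaks <- runif(n_spots, params$spot_peak_intensity[1],
                        params$spot_peak_intensity[2])
    spot_img <- .render_spots(H, W, spots$x, spots$y,
                              params$spot_sigma_px, spot_peaks)

    green_clean <- params$bg_level + params$bleed_alpha * red_clean + spot_img
    if (params$noise_sd > 0) {
      red <- red_clean + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
      green <- green_clean + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
      red <- pmax(red, 0); green <- pmax(green, 0)
    } else {
      red <- red_clean; green <- green_clean
    }

    field <- structure(list(
      green = green, red = red, pixel_size_um = params$pixel_size_um,
      field_id = field_id, mouse_id = mouse_id
    ), class = "TwoChannelField")
    truth <- structure(list(
      follicle_centers = centers, follicle_radii = radii,
      follicle_peaks = peaks, mcsc_positions = spots,
      mcsc_peaks = spot_peaks, bleed_alpha = params$bleed_alpha,
      params = params
    ), class = "SyntheticTruth")
    list(field = field, truth = truth)
  })
}

# Jittered hexagonal placement with minimum separation 2.5 * max radius and a
# one-max-radius margin so blobs stay inside the field. Murine follicles are
# quasi-regular, and the separation guarantees detections never merge.
place_follicles <- function(params) {
  n <- params$n_follicles
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  W <- params$width_px; H <- params$height_px
  rmax <- max(params$follicle_radius_px)
  min_sep <- 2.5 * rmax
  margin <- rmax + 1
  uw <- W - 1 - 2 * margin; uh <- H - 1 - 2 * margin
  if (uw <= 0 || uh <= 0)
    stop_mcsc("mcsc_placement_error", "field too small for follicle margin")

  s <- sqrt(uw * uh / (0.866 * n * 1.15))
  grid <- NULL
  for (try in 1:60) {
    if (s < min_sep) break
    grid <- hex_grid(uw, uh, s)
    if (nrow(grid) >= n) break
    s <- s * 0.95
  }
  if (is.null(grid) || nrow(grid) < n || s < min_sep)
    stop_mcsc("mcsc_placement_error",
              sprintf("cannot place %d follicles with separation %.1f px in %dx%d field",
                      n, min_sep, W, H))
  jit <- max(0, (s - min_sep) / (2 * sqrt(2)))
  pick <- sample.int(nrow(grid), n)
  x <- grid$x[pick] + runif(n, -jit, jit) + margin
  y <- grid$y[pick] + runif(n, -jit, jit) + margin
  data.frame(x = pmin(pmax(x, margin), W - 1 - margin),
             y = pmin(pmax(y, margin), H - 1 - margin))
}

hex_grid <- function(uw, uh, s) {
  dy <- s * sqrt(3) / 2
  ys <- seq(0, uh, by = dy)
  pts <- lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) s / 2 else 0
    xs <- seq(off, uw, by = s)
    if (length(xs) == 0) return(NULL)
    data.frame(x = xs, y = ys[r])
  })
  do.call(rbind, pts)
}

#' Simulate a whole-mount dataset for one mouse
#'
#' Generates `n_fields` independent fields sharing one `mouse_id`, with field
#' seeds `base_seed, base_seed + 1, ...`. The default of 20 fields at 320
#' follicles each reproduces the per-mouse quantification basis of 6400
#' hair follicles.
#'
#' @param params a [field_params()] object (its `seed` is ignored in favour of
#'   `base_seed + i - 1` for field `i`).
#' @param n_fields number of fields (default 20).
#' @param base_seed seed of the first field.
#' @param mouse_id mouse identifier.
#' @return List of `n_fields` elements, each as in [generate_wholemount()].
#' @export
generate_mouse_dataset <- function(params, n_fields = 20L, base_seed = 1L,
                                   mouse_id = "mouse01") {
  assert_scalar_num(n_fields, "n_fields", lower = 1)
  lapply(seq_len(n_fields), function(i) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    generate_wholemount(p, field_id = sprintf("%s_f%02d", mouse_id, i),
                        mouse_id = mouse_id)
  })
}

#' Simulate per-mouse migration rates from the Poisson count model
#'
#' Draws per-mouse total melanocyte counts as
#' Poisson(`follicles_per_mouse * rate`) and returns the implied migration
#' rates (counts over follicles). This is the count-level view of the image
#' generator — the same law that governs spot placement — and is the fast
#' population model used for statistical calibration.
#'
#' @param n_mice number of mice.
#' @param rate true melanocytes-per-follicle rate.
#' @param follicles_per_mouse follicles quantified per mouse (default 6400).
#' @param seed integer seed.
#' @return Numeric vector of `n_mice` migration rates.
#' @export
simulate_migration_rates <- function(n_mice, rate, follicles_per_mouse = 6400,
                                     seed = 1L) {
  assert_scalar_num(n_mice, "n_mice", lower = 1)
  assert_scalar_num(rate, "rate", lower = 0)
  with_seed(seed, rpois(n_mice, follicles_per_mouse * rate) / follicles_per_mouse)
}
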