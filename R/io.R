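#' Write a two-channel field as a 16-bit multi-page TIFF
#'
#' Page order is green first, red second (override on read via
#' `channel_map`). Intensities are clipped to `[0, 65535]` and stored at
#' 16-bit depth, so a round trip quantizes values to the nearest integer.
#'
#' @param field a `TwoChannelField`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "TwoChannelField"))
    stop_mcsc("mcsc_validation_error", "'field' must be a TwoChannelField")
  clip <- function(m) round(pmin(pmax(m, 0), 65535)) / 65535
  tiff::writeTIFF(list(clip(field$green), clip(field$red)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel field from a multi-page TIFF
#'
#' @param path TIFF path. By default `mouse_id` and `field_id` are parsed
#'   from a `<mouse>_<field>.tif` filename; both can be overridden.
#' @param channel_map named integer vector giving the (1-based) page of each
#'   channel, default `c(green = 1, red = 2)`.
#' @param pixel_size_um pixel size recorded on the field.
#' @param mouse_id,field_id identifier overrides.
#' @return A `TwoChannelField` with intensities on the 0-65535 scale.
#' @export
read_field <- function(path, channel_map = c(green = 1L, red = 2L),
                       pixel_size_um = 1.0, mouse_id = NULL,
                       field_id = NULL) {
  if (!file.exists(path))
    stop_mcsc("mcsc_format_error", sprintf("no such file: %s", path))
  if (!all(c("green", "red") %in% names(channel_map)))
    stop_mcsc("mcsc_validation_error", "channel_map needs 'green' and 'red'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < max(channel_map))
    stop_mcsc("mcsc_format_error",
              sprintf("%s has %d page(s); channel map needs page %d",
                      path, length(pages), max(channel_map)))
  as_mat <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # greyscale stored with channels
    p * 65535
  }
  green <- as_mat(pages[[channel_map[["green"]]]])
  red <- as_mat(pages[[channel_map[["red"]]]])
  if (!identical(dim(green), dim(red)))
    stop_mcsc("mcsc_format_error", sprintf("%s: channel shapes differ", path))
  stem <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  structure(list(
    green = green, red = red, pixel_size_um = pixel_size_um,
    field_id = if (is.null(field_id)) stem else field_id,
    mouse_id = if (is.null(mouse_id)) parts[1] else mouse_id
  ), class = "TwoChannelField")
}

#' Write generator ground truth as CSV tables
#'
#' Writes `<stem>_follicles.csv` (x_px, y_px, radius_px) and
#' `<stem>_spots.csv` (x_px, y_px) next to the image they describe.
#'
#' @param truth a `SyntheticTruth`.
#' @param stem output path stem (no extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_truth_csv <- function(truth, stem) {
  fol <- data.frame(x_px = truth$follicle_centers$x,
                    y_px = truth$follicle_centers$y,
                    radius_px = truth$follicle_radii)
  sp <- data.frame(x_px = truth$mcsc_positions$x,
                   y_px = truth$mcsc_positions$y)
  p1 <- paste0(stem, "_follicles.csv"); p2 <- paste0(stem, "_spots.csv")
  write.csv(fol, p1, row.names = FALSE)
  write.csv(sp, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Default run configuration for the end-to-end pipeline
#'
#' A `RunConfig` collects everything [run_pipeline()] needs: channel
#' conventions, detection parameters, the simulation design (groups of mice
#' with their true rates), statistics options, and the master seed. It
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]); unknown top-level keys are rejected on read.
#'
#' @param ... overrides of top-level entries (nested lists are merged).
#' @return Object of class `RunConfig`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    channels = list(green_page = 1L, red_page = 2L),
    detection = unclass(quant_config()),
    simulation = list(
      enabled = TRUE,
      field = list(width_px = 2048L, height_px = 2048L, n_follicles = 320L,
                   mcsc_rate = 0.05, bleed_alpha = 0.30, bg_level = 100,
                   noise_sd = 10),
      n_fields = 20L,
      groups = list(list(name = "ctrl", n_mice = 2L))
    ),
    stats = list(test = "welch_t", alpha = 0.05),
    seed = 1L,
    log_level = "info"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop_mcsc("mcsc_validation_error",
              paste("unknown config keys:", paste(bad, collapse = ", ")))
  structure(modifyList(cfg, dots), class = "RunConfig")
}

#' @rdname default_run_config
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_mcsc("mcsc_format_error", sprintf("no such config: %s", path))
  raw <- yaml::read_yaml(path)
  base <- default_run_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stop_mcsc("mcsc_validation_error",
              paste("unknown config keys:", paste(bad, collapse = ", ")))
  structure(modifyList(unclass(base), raw), class = "RunConfig")
}
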