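#' Quantify one whole-mount field end to end
#'
#' Composes the whole-mount chain: follicle detection in the red channel,
#' bleed-through estimation over the dilated follicle footprints, green
#' unmixing, and spot detection in the corrected green channel. Instead of
#' manual, by-eye correction of counts, the pipeline supports exporting a QC
#' overlay ([write_qc_overlay()]) so a human can audit detections without
#' editing them.
#'
#' Degenerate fields (constant channels, no usable follicle mask) return a
#' zero-count record with explanatory flags rather than failing, so a run
#' over many fields always completes.
#'
#' @param field a `TwoChannelField` (see [generate_wholemount()] or
#'   [read_field()]).
#' @param config a [quant_config()] object or override list.
#' @return Object of class `FieldQuantification`: `record` (one-row
#'   data.frame with `field_id`, `mouse_id`, `n_follicles`, `n_mcsc`,
#'   `alpha`, `intercept`, `flags`), plus the intermediate `follicles`,
#'   `model`, and `spots` objects.
#' @examples
#' sim <- generate_wholemount(field_params(width_px = 512, height_px = 512,
#'                                         n_follicles = 12, mcsc_rate = 0.5,
#'                                         seed = 5))
#' quantify_field(sim$field)$record
#' @export
quantify_field <- function(field, config = quant_config()) {
  if (!inherits(field, "TwoChannelField"))
    stop_mcsc("mcsc_validation_error", "'field' must be a TwoChannelField")
  cfg <- as_quant_config(config)
  fol <- detect_follicles(field$red, cfg, field_id = field$field_id)
  flags <- fol$flags
  model <- NULL; spots <- NULL
  n_mcsc <- 0L
  if (!"low_contrast" %in% flags) {
    brush <- EBImage::makeBrush(2L * as.integer(cfg$bleed$dilate_px) + 1L, "disc")
    mask <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(fol$mask * 1), brush)) > 0
    model <- tryCatch(estimate_bleed(field$red, field$green, mask, cfg),
                      mcsc_error = function(e) e)
    if (inherits(model, "mcsc_error")) {
      flags <- c(flags, paste0("bleed_fit_failed:", class(model)[1]))
      model <- NULL
    }
  }
  if (!is.null(model)) {
    if (model$alpha > cfg$max_alpha) flags <- c(flags, "suspect_channel_order")
    corrected <- unmix_green(field$green, field$red, model)
    spots <- detect_mcsc_spots(corrected, cfg, field_id = field$field_id)
    n_mcsc <- spots$count
  }
  record <- data.frame(
    field_id = field$field_id, mouse_id = field$mouse_id,
    n_follicles = fol$count, n_mcsc = n_mcsc,
    alpha = if (is.null(model)) NA_real_ else model$alpha,
    intercept = if (is.null(model)) NA_real_ else model$intercept,
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
  structure(list(record = record, follicles = fol, model = model,
                 spots = spots),
            class = "FieldQuantification")
}

#' @export
print.FieldQuantification <- function(x, ...) {
  cat(sprintf("FieldQuantification [%s]: %d follicles, %d McSCs (alpha %.3f)\n",
              x$record$field_id, x$record$n_follicles, x$record$n_mcsc,
              x$record$alpha))
  invisible(x)
}

#' Quantify a list of fields into a per-field record table
#'
#' Runs [quantify_field()] over each field; a failing field is recorded with
#' NA counts and an `error:` flag and the run continues.
#'
#' @param fields list of `TwoChannelField` objects (or of
#'   `generate_wholemount()`-style lists carrying a `$field`).
#' @param config a [quant_config()] object or override list.
#' @return data.frame with one row per field (the `ImageRecord` table).
#' @export
quantify_dataset <- function(fields, config = quant_config()) {
  rows <- lapply(fields, function(f) {
    if (!inherits(f, "TwoChannelField") && !is.null(f$field)) f <- f$field
    tryCatch(quantify_field(f, config)$record, error = function(e)
      data.frame(field_id = f$field_id, mouse_id = f$mouse_id,
                 n_follicles = NA_integer_, n_mcsc = NA_integer_,
                 alpha = NA_real_, intercept = NA_real_,
                 flags = paste0("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Write a QC overlay image of the detections
#'
#' Renders both channels as an RGB PNG (red channel in red, green channel in
#' green) with detected follicle centroids marked as blue crosses and
#' detected spots as white crosses, for human audit of the automatic counts.
#' Requires the `png` package.
#'
#' @param field a `TwoChannelField`.
#' @param quant a `FieldQuantification` for that field.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(field, quant, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_mcsc("mcsc_validation_error", "QC overlays require the 'png' package")
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) <= 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  H <- nrow(field$red); W <- ncol(field$red)
  rgb <- array(0, c(H, W, 3))
  rgb[, , 1] <- norm01(field$red)
  rgb[, , 2] <- norm01(field$green)
  draw_cross <- function(rgb, x, y, col) {
    for (k in seq_along(x)) {
      r <- round(y[k]) + 1L; c <- round(x[k]) + 1L
      rr <- pmin(pmax(r + (-3:3), 1L), H); cc <- pmin(pmax(c + (-3:3), 1L), W)
      for (ch in 1:3) {
        rgb[rr, c, ch] <- col[ch]
        rgb[r, cc, ch] <- col[ch]
      }
    }
    rgb
  }
  fc <- quant$follicles$centroids
  rgb <- draw_cross(rgb, fc$x, fc$y, c(0, 0.4, 1))
  if (!is.null(quant$spots) && quant$spots$count > 0) {
    sc <- quant$spots$centroids
    rgb <- draw_cross(rgb, sc$x, sc$y, c(1, 1, 1))
  }
  png::writePNG(rgb, path)
  invisible(path)
}
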