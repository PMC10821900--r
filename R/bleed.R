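#' Estimate red-to-green bleed-through from autofluorescent pixels
#'
#' Hair-follicle autofluorescence appears in both channels; over spot-free
#' follicle pixels the green intensity is linear in red with slope equal to
#' the bleed-through coefficient. The slope is fitted robustly (Theil-Sen by
#' default) so that the rare GFP spots falling inside the mask do not bias
#' it; the intercept is the residual green background.
#'
#' @param red,green numeric matrices of identical shape.
#' @param follicle_mask logical matrix marking autofluorescent pixels (e.g.
#'   the dilated follicle mask from [detect_follicles()]).
#' @param config a [quant_config()] object or override list.
#' @return Object of class `UnmixModel` with `alpha`, `intercept`,
#'   `n_pixels_used` and `fit_diagnostic` (MAD of fit residuals).
#' @export
estimate_bleed <- function(red, green, follicle_mask,
                           config = quant_config()) {
  assert_image(red, "red"); assert_image(green, "green")
  assert_same_shape(red, green)
  assert_same_shape(red, follicle_mask, "image and mask")
  cfg <- as_quant_config(config)$bleed
  idx <- which(follicle_mask)
  if (length(idx) < cfg$min_pixels)
    stop_mcsc("mcsc_insufficient_data",
              sprintf("bleed mask has %d pixels; need >= %d",
                      length(idx), cfg$min_pixels))
  # deterministic, evenly spaced subsample
  if (length(idx) > cfg$max_points)
    idx <- idx[unique(round(seq(1, length(idx), length.out = cfg$max_points)))]
  r <- red[idx]; g <- green[idx]
  if (diff(range(r)) <= .Machine$double.eps)
    stop_mcsc("mcsc_degenerate_fit", "red channel is constant over the mask")

  if (identical(cfg$method, "lsq")) {
    fit <- stats::lm.fit(cbind(1, r), g)
    alpha <- unname(fit$coefficients[2])
    intercept <- unname(fit$coefficients[1])
  } else {
    dx <- outer(r, r, "-"); dy <- outer(g, g, "-")
    keep <- upper.tri(dx) & dx != 0
    if (!any(keep))
      stop_mcsc("mcsc_degenerate_fit", "no pixel pairs with distinct red values")
    alpha <- median(dy[keep] / dx[keep])
    intercept <- median(g - alpha * r)
  }
  resid <- g - alpha * r - intercept
  structure(list(
    alpha = alpha, intercept = intercept,
    n_pixels_used = length(idx), fit_diagnostic = mad(resid)
  ), class = "UnmixModel")
}

#' @export
print.UnmixModel <- function(x, ...) {
  cat(sprintf("UnmixModel: alpha %.4f, intercept %.2f (%d px, resid MAD %.2f)\n",
              x$alpha, x$intercept, x$n_pixels_used, x$fit_diagnostic))
  invisible(x)
}

#' Remove bleed-through from the green channel
#'
#' Balances the red-channel autofluorescence out of the green channel:
#' `corrected = max(green - alpha * red - intercept, 0)`. On a field that
#' follows the linear bleed model exactly, the corrected image is the pure
#' spot image.
#'
#' @param green,red numeric matrices of identical shape.
#' @param model an `UnmixModel` from [estimate_bleed()], or a list with
#'   `alpha` and `intercept`.
#' @return Corrected green matrix (non-negative, same shape).
#' @export
unmix_green <- function(green, red, model) {
  assert_image(green, "green"); assert_image(red, "red")
  assert_same_shape(green, red)
  if (is.null(model$alpha) || is.null(model$intercept))
    stop_mcsc("mcsc_validation_error", "'model' needs alpha and intercept")
  pmax(green - model$alpha * red - model$intercept, 0)
}
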