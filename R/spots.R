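#' Detect H2B-GFP nuclear point signals in a corrected green channel
#'
#' Multiscale blob detection: the scale-normalised (negative)
#' Laplacian-of-Gaussian response is computed over a small sigma set and
#' maximised across scales; 8-neighbourhood local maxima with positive
#' response whose corrected-image intensity exceeds a robust background
#' threshold (`threshold_k` robust background MADs above the background
#' centre, or an absolute level) are candidate nuclei, then non-maximum
#' suppression keeps only the strongest maximum within `min_separation_px`
#' (ties broken towards smaller (y, x)). Each surviving point is one
#' migrated melanocyte. The background scale falls back to an upper-quantile
#' estimate when the image is zero-clipped over most of its area, as
#' unmixed green channels are.
#'
#' @param corrected_green non-negative numeric matrix, normally from
#'   [unmix_green()].
#' @param config a [quant_config()] object or override list.
#' @param field_id identifier carried into the result.
#' @return Object of class `SpotDetections`: `centroids` (0-based x, y),
#'   `peak_intensities` (corrected-image values at the maxima), `count`,
#'   `field_id`. Zero detections is a valid result.
#' @export
detect_mcsc_spots <- function(corrected_green, config = quant_config(),
                              field_id = "field01") {
  assert_image(corrected_green, "corrected_green")
  cfg <- as_quant_config(config)$spot
  empty <- structure(list(
    centroids = data.frame(x = numeric(0), y = numeric(0)),
    peak_intensities = numeric(0), count = 0L, field_id = field_id
  ), class = "SpotDetections")
  if (diff(range(corrected_green)) <= .Machine$double.eps) return(empty)

  resp <- NULL
  for (s in cfg$sigmas) {
    r <- log_response(corrected_green, s)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  thr <- if (!is.null(cfg$threshold_abs) && !is.na(cfg$threshold_abs))
    cfg$threshold_abs
  else {
    bg <- robust_background(corrected_green)
    bg[["center"]] + cfg$threshold_k * bg[["scale"]]
  }
  ismax <- .local_maxima8(resp)
  idx <- which(ismax & resp > 0 & corrected_green > thr)
  if (length(idx) == 0L) return(empty)
  if (length(idx) > 10000L)  # keep suppression tractable on degenerate input
    idx <- idx[order(resp[idx], decreasing = TRUE)[1:10000]]
  H <- nrow(resp)
  y <- (idx - 1L) %% H          # 0-based row
  x <- (idx - 1L) %/% H         # 0-based column
  v <- resp[idx]
  # non-maximum suppression: strongest first, ties by (y, x)
  ord <- order(-v, y, x)
  x <- x[ord]; y <- y[ord]; v <- v[ord]; idx <- idx[ord]
  keep <- logical(length(x))
  min_sep2 <- cfg$min_separation_px^2
  for (k in seq_along(x)) {
    sel <- which(keep)
    if (!length(sel) ||
        all((x[sel] - x[k])^2 + (y[sel] - y[k])^2 >= min_sep2))
      keep[k] <- TRUE
  }
  centroids <- data.frame(x = as.numeric(x[keep]), y = as.numeric(y[keep]))
  o <- order(centroids$y, centroids$x)
  structure(list(
    centroids = centroids[o, , drop = FALSE],
    peak_intensities = corrected_green[idx[keep]][o],
    count = sum(keep), field_id = field_id
  ), class = "SpotDetections")
}

#' @export
print.SpotDetections <- function(x, ...) {
  cat(sprintf("SpotDetections [%s]: %d spots\n", x$field_id, x$count))
  invisible(x)
}
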