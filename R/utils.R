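#' @useDynLib mcscquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats mad median quantile rnorm rpois runif sd t.test wilcox.test
#' @importFrom utils head modifyList read.csv write.csv
NULL

# Classed error helper so callers can condition on failure mode.
stop_mcsc <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mcsc_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_mcsc("mcsc_validation_error", sprintf("'%s' must be a numeric matrix", name))
  if (anyNA(x) || any(!is.finite(x)))
    stop_mcsc("mcsc_validation_error", sprintf("'%s' contains non-finite values", name))
  if (any(x < 0))
    stop_mcsc("mcsc_validation_error", sprintf("'%s' has negative intensities", name))
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_mcsc("mcsc_validation_error",
              sprintf("%s have different shapes (%s vs %s)", what,
                      paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(NULL)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok)
    stop_mcsc("mcsc_validation_error",
              sprintf("'%s' must be a finite scalar in %s%s, %s]", name,
                      if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit seed and leave
#' the caller's random-number state untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Otsu threshold via EBImage on an arbitrary-range matrix. Returns the
# threshold on the original intensity scale, or NA for a constant image.
# Large images are subsampled on a regular stride: the 256-bin histogram the
# criterion works on is unchanged statistically and the cost stays flat.
otsu_threshold <- function(img, max_pixels = 500000L) {
  v <- as.vector(img)
  if (length(v) > max_pixels)
    v <- v[seq(1L, length(v), by = ceiling(length(v) / max_pixels))]
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(NA_real_)
  scaled <- matrix((v - rng[1]) / diff(rng), ncol = 1)
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + thr01 * diff(rng)
}

# Robust background centre and scale for a possibly zero-clipped intensity
# image. The plain MAD collapses to zero when more than half the pixels sit
# at the clip value, so fall back to the upper-quantile spread
# (q97.5 - median) / 1.96, which only assumes the upper background tail is
# Gaussian and is insensitive to sparse bright signal.
robust_background <- function(x) {
  ctr <- median(x)
  sc_mad <- mad(x, center = ctr)
  sc_q <- (quantile(x, 0.975, names = FALSE) - ctr) / stats::qnorm(0.975)
  c(center = ctr, scale = max(sc_mad, sc_q, 0))
}

# Foreground mask for one channel: "otsu" (default), a fixed absolute level,
# or an intensity quantile. `level` uses NA for "unset".
threshold_mask <- function(img, method = "otsu", level = NA_real_) {
  unset <- is.null(level) || is.na(level)
  if (identical(method, "absolute")) {
    if (unset)
      stop_mcsc("mcsc_validation_error", "absolute thresholding needs 'level'")
    return(img > level)
  }
  if (identical(method, "quantile")) {
    if (unset)
      stop_mcsc("mcsc_validation_error", "quantile thresholding needs 'level'")
    return(img > quantile(img, level))
  }
  thr <- otsu_threshold(img)
  if (is.na(thr)) return(matrix(FALSE, nrow(img), ncol(img)))
  img > thr
}

# Label connected components (4-connectivity, matching EBImage::bwlabel) and
# return a list with the label matrix, component areas and centroids in
# 0-based (x = column, y = row) pixel coordinates.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab, n = 0L, areas = integer(0),
                centroids = data.frame(x = numeric(0), y = numeric(0))))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  areas <- tabulate(l, nbins = n)
  cx <- rowsum(as.numeric(cols), l)[, 1] / areas - 1
  cy <- rowsum(as.numeric(rows), l)[, 1] / areas - 1
  list(labels = lab, n = as.integer(n), areas = as.integer(areas),
       centroids = data.frame(x = cx, y = cy))
}

# Greedy minimum-distance matching between two centroid sets under a gate.
# Pairs are taken in increasing distance order; each point used at most once.
# With detections well separated relative to the gate this equals the optimal
# assignment. Returns a data.frame of (i, j, dist).
match_points <- function(a, b, max_dist = 3) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  d <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  d <- sqrt(d)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(i = cand[, 1], j = cand[, 2],
             dist = d[cbind(cand[, 1], cand[, 2])])
}

# 1-D Gaussian kernel (unit sum) and its exact second derivative, both
# truncated at `cutoff` sigmas; odd length.
gaussian_kernel <- function(sigma, cutoff = 4) {
  h <- max(1L, as.integer(ceiling(cutoff * sigma)))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_d2_kernel <- function(sigma, cutoff = 4) {
  h <- max(2L, as.integer(ceiling(cutoff * sigma)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  (x^2 - sigma^2) / sigma^4 * g
}

# Scale-normalised negative Laplacian-of-Gaussian response (bright blobs give
# positive peaks).
log_response <- function(img, sigma) {
  g <- gaussian_kernel(sigma)
  d2 <- gaussian_d2_kernel(sigma)
  r <- .conv_sep(img, d2, g) + .conv_sep(img, g, d2)
  -sigma^2 * r
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gaussian_kernel(sigma)
  .conv_sep(img, g, g)
}
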