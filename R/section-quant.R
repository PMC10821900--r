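#' Positive-staining area over DAPI area
#'
#' Quantifies relative staining on a sectioned-tissue image pair as the
#' thresholded positive-stain area divided by the thresholded DAPI
#' (counterstain) area, the standard normalization when cell-by-cell
#' segmentation is not feasible. Thresholding is per-channel (Otsu default,
#' absolute or quantile override via `config$cell$threshold`).
#'
#' An image whose DAPI foreground is empty raises a classed error rather
#' than returning zero: the ratio is undefined there, and a silent zero
#' would bias group means downward.
#'
#' @param stain,dapi numeric matrices of identical shape.
#' @param config a [quant_config()] object or override list.
#' @param image_id identifier carried into the result.
#' @return Object of class `AreaRatioResult`: `positive_area_px`,
#'   `dapi_area_px`, `ratio`, `image_id`, plus the two binary masks.
#' @examples
#' sp <- generate_section_pair(200, 200, 0.1, 0.4, noise_sd = 0, seed = 1)
#' area_ratio(sp$stain, sp$dapi)$ratio
#' @export
area_ratio <- function(stain, dapi, config = quant_config(),
                       image_id = "image01") {
  assert_image(stain, "stain"); assert_image(dapi, "dapi")
  assert_same_shape(stain, dapi)
  cfg <- as_quant_config(config)$cell
  dapi_mask <- threshold_mask(dapi, cfg$threshold, cfg$threshold_level)
  if (!any(dapi_mask))
    stop_mcsc("mcsc_empty_dapi",
              "DAPI foreground is empty; area ratio undefined")
  stain_mask <- if (diff(range(stain)) <= .Machine$double.eps)
    matrix(FALSE, nrow(stain), ncol(stain))
  else threshold_mask(stain, cfg$threshold, cfg$threshold_level)
  pos <- sum(stain_mask); dap <- sum(dapi_mask)
  structure(list(
    positive_area_px = as.integer(pos), dapi_area_px = as.integer(dap),
    ratio = pos / dap, image_id = image_id,
    stain_mask = stain_mask, dapi_mask = dapi_mask
  ), class = "AreaRatioResult")
}

#' @export
print.AreaRatioResult <- function(x, ...) {
  cat(sprintf("AreaRatioResult [%s]: %d / %d px = %.4f\n", x$image_id,
              x$positive_area_px, x$dapi_area_px, x$ratio))
  invisible(x)
}

#' Count stained cells per image
#'
#' Thresholds the stain channel, labels connected components and counts those
#' whose area falls inside the configured cell-size gate — the
#' cells-per-image measure used for e.g. T-cell infiltration. Zero is a valid
#' count.
#'
#' @param stain non-negative numeric matrix.
#' @param config a [quant_config()] object or override list (gate:
#'   `config$cell$min_area` / `max_area`).
#' @param image_id identifier.
#' @return Object of class `FrameCount`: `image_id`, `n_cells`, `centroids`.
#' @export
count_cells <- function(stain, config = quant_config(), image_id = "image01") {
  assert_image(stain, "stain")
  cfg <- as_quant_config(config)$cell
  if (diff(range(stain)) <= .Machine$double.eps)
    return(structure(list(image_id = image_id, n_cells = 0L,
                          centroids = data.frame(x = numeric(0), y = numeric(0))),
                     class = "FrameCount"))
  mask <- threshold_mask(stain, cfg$threshold, cfg$threshold_level)
  comp <- label_components(mask)
  keep <- comp$areas >= cfg$min_area & comp$areas <= cfg$max_area
  centroids <- comp$centroids[keep, , drop = FALSE]
  rownames(centroids) <- NULL
  structure(list(image_id = image_id, n_cells = nrow(centroids),
                 centroids = centroids),
            class = "FrameCount")
}

#' Object-based colocalization of two spot sets
#'
#' A reference spot counts as colocalized when at least one other-channel
#' spot lies within `match_radius_px` of its centroid (one-to-many matching:
#' a single nucleus in the other channel may validate several reference spots;
#' duplicates are prevented upstream by spot non-maximum suppression). Used
#' e.g. for EdU incorporation in reporter-labelled melanocyte nuclei, where
#' both signals are nuclear and point-like.
#'
#' @param spots_ref,spots_other data.frames with columns `x`, `y` (px).
#' @param match_radius_px positive matching radius; default 3 px, about one
#'   nuclear radius.
#' @return Object of class `ColocResult`: `n_ref`, `n_coloc`, `fraction`,
#'   `match_radius_px`, `flags`. An empty reference set gives fraction 0 with
#'   an `empty_reference` flag.
#' @export
colocalization_fraction <- function(spots_ref, spots_other,
                                    match_radius_px = 3) {
  assert_scalar_num(match_radius_px, "match_radius_px", lower = 0,
                    strict_lower = TRUE)
  for (s in list(spots_ref, spots_other))
    if (!is.data.frame(s) || !all(c("x", "y") %in% names(s)))
      stop_mcsc("mcsc_validation_error", "spot sets need columns 'x' and 'y'")
  n_ref <- nrow(spots_ref)
  if (n_ref == 0L)
    return(structure(list(n_ref = 0L, n_coloc = 0L, fraction = 0,
                          match_radius_px = match_radius_px,
                          flags = "empty_reference"), class = "ColocResult"))
  n_coloc <- 0L
  if (nrow(spots_other) > 0L) {
    d2 <- outer(spots_ref$x, spots_other$x, "-")^2 +
      outer(spots_ref$y, spots_other$y, "-")^2
    n_coloc <- sum(apply(d2, 1, min) <= match_radius_px^2)
  }
  structure(list(n_ref = as.integer(n_ref), n_coloc = as.integer(n_coloc),
                 fraction = n_coloc / n_ref,
                 match_radius_px = match_radius_px, flags = character(0)),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: %d / %d colocalized (%.3f) at radius %.1f px\n",
              x$n_coloc, x$n_ref, x$fraction, x$match_radius_px))
  invisible(x)
}
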