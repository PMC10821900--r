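#' Simulate a stain/DAPI section image pair with exact area truth
#'
#' Paints a DAPI nuclear-counterstain region and a positive-stain region that
#' is a strict subset of it (subset mode), or `n_cells` disjoint cell-sized
#' blobs (cell mode). Mask areas are painted exactly — the truth areas are the
#' painted pixel counts — then converted to intensity images as
#' `bg + fg * mask + noise`.
#'
#' @param width_px,height_px image size.
#' @param stain_fraction fraction of the image painted as positive stain
#'   (subset mode); must not exceed `dapi_fraction`.
#' @param dapi_fraction fraction of the image painted as DAPI foreground.
#' @param n_cells number of disjoint cell blobs (cell mode); when > 0 the
#'   stain channel holds the cells and `stain_fraction` is ignored.
#' @param cell_radius_px cell blob radius in px (cell mode).
#' @param bg_level,fg_level background and foreground intensities.
#' @param noise_sd additive Gaussian noise sd (0 for noise-free).
#' @param seed integer seed.
#'
#' @return List with `stain` and `dapi` intensity matrices, logical masks
#'   `stain_mask`/`dapi_mask`, and `truth` (class `SectionPairTruth`:
#'   `stain_mask_area_px`, `dapi_mask_area_px`, `n_cells`).
#' @examples
#' sp <- generate_section_pair(200, 200, stain_fraction = 0.1,
#'                             dapi_fraction = 0.4, noise_sd = 0, seed = 1)
#' sp$truth$stain_mask_area_px / sp$truth$dapi_mask_area_px
#' @export
generate_section_pair <- function(width_px, height_px,
                                  stain_fraction = 0.1, dapi_fraction = 0.4,
                                  n_cells = 0L, cell_radius_px = 5,
                                  bg_level = 20, fg_level = 200,
                                  noise_sd = 10, seed = 1L) {
  assert_scalar_num(stain_fraction, "stain_fraction", lower = 0, upper = 1)
  assert_scalar_num(dapi_fraction, "dapi_fraction", lower = 0, upper = 1,
                    strict_lower = TRUE)
  if (n_cells == 0L && stain_fraction > dapi_fraction)
    stop_mcsc("mcsc_validation_error",
              "stain_fraction must not exceed dapi_fraction (stain is a DAPI subset)")
  W <- as.integer(width_px); H <- as.integer(height_px)
  npx <- W * H
  with_seed(seed, {
    # Rank pixels by distance from the image centre; taking the first k gives
    # a disc-like region, and nested k give exactly nested masks.
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    d2 <- outer(((0:(H - 1)) - cy)^2, ((0:(W - 1)) - cx)^2, "+")
    ord <- order(d2)
    k_dapi <- round(dapi_fraction * npx)
    dapi_mask <- matrix(FALSE, H, W)
    dapi_mask[ord[seq_len(k_dapi)]] <- TRUE

    stain_mask <- matrix(FALSE, H, W)
    if (n_cells > 0L) {
      cells <- place_cells(W, H, n_cells, cell_radius_px)
      for (i in seq_len(n_cells)) {
        xs <- max(0, floor(cells$x[i] - cell_radius_px)):
              min(W - 1, ceiling(cells$x[i] + cell_radius_px))
        ys <- max(0, floor(cells$y[i] - cell_radius_px)):
              min(H - 1, ceiling(cells$y[i] + cell_radius_px))
        dd <- outer((ys - cells$y[i])^2, (xs - cells$x[i])^2, "+")
        stain_mask[ys + 1, xs + 1] <- stain_mask[ys + 1, xs + 1] |
          (dd <= cell_radius_px^2)
      }
    } else if (stain_fraction > 0) {
      k_stain <- round(stain_fraction * npx)
      stain_mask[ord[seq_len(k_stain)]] <- TRUE
    }

    stain <- bg_level + fg_level * stain_mask
    dapi <- bg_level + fg_level * dapi_mask
    if (noise_sd > 0) {
      stain <- pmax(stain + matrix(rnorm(npx, 0, noise_sd), H, W), 0)
      dapi <- pmax(dapi + matrix(rnorm(npx, 0, noise_sd), H, W), 0)
    }
    truth <- structure(list(
      stain_mask_area_px = sum(stain_mask),
      dapi_mask_area_px = sum(dapi_mask),
      n_cells = as.integer(n_cells)
    ), class = "SectionPairTruth")
    list(stain = stain, dapi = dapi, stain_mask = stain_mask,
         dapi_mask = dapi_mask, truth = truth)
  })
}

# Disjoint cell centres on a jittered grid with separation > 3 radii.
place_cells <- function(W, H, n, radius) {
  sep <- 3.5 * radius
  margin <- radius + 1
  grid <- expand.grid(
    x = seq(margin, W - 1 - margin, by = sep),
    y = seq(margin, H - 1 - margin, by = sep)
  )
  if (nrow(grid) < n)
    stop_mcsc("mcsc_placement_error",
              sprintf("cannot place %d disjoint cells of radius %.1f in %dx%d",
                      n, radius, W, H))
  jit <- max(0, (sep - 2.2 * radius) / (2 * sqrt(2)))
  pick <- sample.int(nrow(grid), n)
  data.frame(x = grid$x[pick] + runif(n, -jit, jit),
             y = grid$y[pick] + runif(n, -jit, jit))
}

#' Simulate a two-channel spot pattern with known colocalization fraction
#'
#' Places `n_ref` well-separated reference spots (channel A). A fraction
#' `coloc_fraction` of them (rounded) receives a channel-B partner within
#' `offset_px`; the remaining B spots are placed at least `far_px` from every
#' A spot, so the true object-based colocalization fraction is exactly
#' `round(n_ref * coloc_fraction) / n_ref`.
#'
#' @param n_ref number of reference (channel A) spots.
#' @param coloc_fraction target fraction of A spots with a B partner.
#' @param offset_px distance between a colocalized pair's centroids.
#' @param width_px,height_px field size.
#' @param far_px minimum distance of non-colocalized B spots from any A spot.
#' @param seed integer seed.
#' @return List with centroid data.frames `spots_a` and `spots_b` (0-based
#'   x, y) and `truth_fraction`.
#' @export
generate_coloc_pair <- function(n_ref, coloc_fraction, offset_px = 1,
                                width_px = 512L, height_px = 512L,
                                far_px = 15, seed = 1L) {
  assert_scalar_num(n_ref, "n_ref", lower = 0)
  assert_scalar_num(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  assert_scalar_num(offset_px, "offset_px", lower = 0)
  with_seed(seed, {
    W <- width_px; H <- height_px
    sep <- max(2 * far_px + 2 * offset_px + 2, 20)
    margin <- offset_px + 2
    grid <- expand.grid(x = seq(margin, W - 1 - margin, by = sep),
                        y = seq(margin, H - 1 - margin, by = sep))
    if (n_ref > 0 && nrow(grid) < n_ref)
      stop_mcsc("mcsc_placement_error",
                sprintf("cannot place %d reference spots at separation %.0f in %dx%d",
                        n_ref, sep, W, H))
    a <- if (n_ref > 0) {
      pick <- sample.int(nrow(grid), n_ref)
      data.frame(x = grid$x[pick], y = grid$y[pick])
    } else data.frame(x = numeric(0), y = numeric(0))

    n_coloc <- round(n_ref * coloc_fraction)
    which_coloc <- if (n_coloc > 0) sample.int(n_ref, n_coloc) else integer(0)
    b_list <- list()
    if (n_coloc > 0) {
      if (offset_px == 0) {
        b_list$paired <- a[which_coloc, , drop = FALSE]
      } else {
        th <- runif(n_coloc, 0, 2 * pi)
        b_list$paired <- data.frame(
          x = pmin(pmax(a$x[which_coloc] + offset_px * cos(th), 0), W - 1),
          y = pmin(pmax(a$y[which_coloc] + offset_px * sin(th), 0), H - 1))
      }
    }
    n_far <- n_ref - n_coloc
    if (n_far > 0) {
      # midpoints between grid columns are >= sep/2 >= far_px from every A spot
      cand <- data.frame(x = grid$x + sep / 2, y = grid$y)
      cand <- cand[cand$x <= W - 1 - margin, , drop = FALSE]
      dmin <- apply(cand, 1, function(p)
        if (nrow(a)) min(sqrt((a$x - p[1])^2 + (a$y - p[2])^2)) else Inf)
      cand <- cand[dmin >= far_px, , drop = FALSE]
      if (nrow(cand) < n_far)
        stop_mcsc("mcsc_placement_error", "cannot place far (non-colocalized) spots")
      pick2 <- sample.int(nrow(cand), n_far)
      b_list$far <- cand[pick2, , drop = FALSE]
    }
    b <- if (length(b_list)) do.call(rbind, b_list) else
      data.frame(x = numeric(0), y = numeric(0))
    rownames(b) <- NULL
    list(spots_a = a, spots_b = b,
         truth_fraction = if (n_ref > 0) n_coloc / n_ref else 0)
  })
}
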