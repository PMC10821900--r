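test_that("whole-mount generation is deterministic and truth-consistent", {
  p <- small_params(seed = 7L)
  a <- generate_wholemount(p)
  b <- generate_wholemount(p)
  expect_identical(a, b)

  tr <- a$truth
  expect_equal(nrow(tr$follicle_centers), p$n_follicles)
  expect_equal(length(tr$follicle_radii), p$n_follicles)
  expect_true(all(tr$follicle_centers$x >= 0 &
                  tr$follicle_centers$x <= p$width_px - 1))
  expect_true(all(tr$follicle_centers$y >= 0 &
                  tr$follicle_centers$y <= p$height_px - 1))
  expect_true(all(tr$mcsc_positions$x >= 0 &
                  tr$mcsc_positions$x <= p$width_px - 1))
  expect_true(all(is.finite(a$field$green)) && all(a$field$green >= 0))
  expect_true(all(is.finite(a$field$red)) && all(a$field$red >= 0))
  expect_identical(dim(a$field$green), dim(a$field$red))

  # follicle centres respect the minimum separation of the layout
  d <- as.matrix(dist(tr$follicle_centers)); diag(d) <- Inf
  expect_gte(min(d), 2.5 * max(p$follicle_radius_px))
})

test_that("an empty parameterisation produces all-zero channels", {
  p <- field_params(width_px = 128, height_px = 128, n_follicles = 0,
                    mcsc_rate = 0, noise_sd = 0, bg_level = 0)
  sim <- generate_wholemount(p)
  expect_true(all(sim$field$green == 0))
  expect_true(all(sim$field$red == 0))
  expect_equal(nrow(sim$truth$follicle_centers), 0)
  expect_equal(nrow(sim$truth$mcsc_positions), 0)
})

test_that("noise-free unmixing residual is spatially constant", {
  p <- small_params(mcsc_rate = 0, noise_sd = 0, seed = 3L)
  sim <- generate_wholemount(p)
  resid <- sim$field$green - p$bleed_alpha * sim$field$red
  expect_equal(max(abs(resid - p$bg_level)), 0)
})

test_that("per-field melanocyte counts follow the Poisson law", {
  # mean 32 per field, as for 320 follicles at rate 0.1
  p <- small_params(n_follicles = 16L, mcsc_rate = 2,
                    width_px = 256L, height_px = 256L)
  counts <- vapply(1:300, function(s) {
    q <- p; q$seed <- s
    nrow(generate_wholemount(q)$truth$mcsc_positions)
  }, numeric(1))
  mu <- 16 * 2
  # mean within 4 sigma of the Poisson expectation
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(mu / 300))
  # chi-squared dispersion test at the 1% level: variance ~ mean
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  lim <- qchisq(c(0.005, 0.995), df = 299)
  expect_gt(disp, lim[1])
  expect_lt(disp, lim[2])
})

test_that("mouse datasets compose per-field generation deterministically", {
  p <- small_params()
  ds <- generate_mouse_dataset(p, n_fields = 3, base_seed = 11,
                               mouse_id = "m1")
  expect_length(ds, 3)
  expect_equal(sum(vapply(ds, function(f)
    nrow(f$truth$follicle_centers), numeric(1))), 3 * p$n_follicles)
  expect_true(all(vapply(ds, function(f) f$field$mouse_id, character(1)) == "m1"))

  p1 <- p; p1$seed <- 11L
  single <- generate_wholemount(p1, field_id = ds[[1]]$field$field_id,
                                mouse_id = "m1")
  expect_identical(ds[[1]], single)
  expect_identical(generate_mouse_dataset(p, 3, 11, "m1"), ds)
})

test_that("section pairs paint exact areas and reject infeasible fractions", {
  sp <- generate_section_pair(200, 200, stain_fraction = 0.10,
                              dapi_fraction = 0.40, noise_sd = 0, seed = 1)
  expect_equal(sp$truth$stain_mask_area_px, round(0.10 * 200 * 200))
  expect_equal(sp$truth$dapi_mask_area_px, round(0.40 * 200 * 200))
  expect_true(all(sp$dapi_mask[sp$stain_mask]))  # stain is a DAPI subset

  sp0 <- generate_section_pair(100, 100, stain_fraction = 0,
                               dapi_fraction = 0.3, noise_sd = 0, seed = 1)
  expect_equal(sp0$truth$stain_mask_area_px, 0)
  expect_true(all(sp0$stain == 20))

  expect_error(generate_section_pair(100, 100, stain_fraction = 0.5,
                                     dapi_fraction = 0.3, seed = 1),
               class = "mcsc_validation_error")
})

test_that("cell-mode sections contain the requested number of components", {
  sp <- generate_section_pair(300, 300, dapi_fraction = 0.5, n_cells = 12,
                              noise_sd = 0, seed = 5)
  expect_equal(sp$truth$n_cells, 12)
  expect_equal(flood_fill_count(sp$stain_mask), 12)
})

test_that("coloc pairs realise the requested colocalization fraction", {
  cp <- generate_coloc_pair(n_ref = 100, coloc_fraction = 0.75,
                            offset_px = 1, width_px = 1024, height_px = 1024,
                            seed = 2)
  expect_equal(cp$truth_fraction, 0.75)
  expect_equal(nrow(cp$spots_a), 100)
  res <- colocalization_fraction(cp$spots_a, cp$spots_b, match_radius_px = 3)
  expect_equal(res$fraction, 0.75)

  cp0 <- generate_coloc_pair(20, 0, seed = 3)
  d2 <- outer(cp0$spots_a$x, cp0$spots_b$x, "-")^2 +
    outer(cp0$spots_a$y, cp0$spots_b$y, "-")^2
  expect_gte(sqrt(min(d2)), 15)

  cp1 <- generate_coloc_pair(20, 1, offset_px = 0, seed = 4)
  expect_setequal(paste(cp1$spots_b$x, cp1$spots_b$y),
                  paste(cp1$spots_a$x, cp1$spots_a$y))
})
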