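test_that("noise-free follicles are counted exactly with accurate centroids", {
  p <- small_params(noise_sd = 0, mcsc_rate = 0, seed = 9L)
  sim <- generate_wholemount(p)
  fol <- detect_follicles(sim$field$red)
  expect_equal(fol$count, p$n_follicles)
  m <- mcscquant:::match_points(fol$centroids, sim$truth$follicle_centers,
                                max_dist = 3)
  expect_equal(nrow(m), p$n_follicles)
  expect_lt(max(m$dist), 2)
})

test_that("degenerate images yield zero counts with a low-contrast flag", {
  z <- matrix(0, 64, 64)
  fol <- detect_follicles(z)
  expect_equal(fol$count, 0)
  expect_true("low_contrast" %in% fol$flags)
  expect_equal(detect_mcsc_spots(z)$count, 0)
})

test_that("component counting agrees with a brute-force flood-fill oracle", {
  withr::with_seed(31L, {
    for (i in 1:20) {
      mask <- matrix(runif(64 * 64) < runif(1, 0.05, 0.45), 64, 64)
      expect_equal(mcscquant:::label_components(mask)$n, flood_fill_count(mask))
    }
  })
  # and on the real detection path of a small clean field
  p <- small_params(n_follicles = 15L, noise_sd = 0, mcsc_rate = 0, seed = 12L)
  sim <- generate_wholemount(p)
  fol <- detect_follicles(sim$field$red)
  expect_equal(fol$count, flood_fill_count(fol$mask))
})

test_that("bleed estimation handles identity, constant and degenerate input", {
  r <- matrix(runif(64 * 64, 10, 200), 64, 64)
  mask <- matrix(TRUE, 64, 64)
  cfg <- quant_config(bleed = list(min_pixels = 50))

  m1 <- estimate_bleed(r, r, mask, cfg)
  expect_equal(m1$alpha, 1)
  expect_equal(m1$intercept, 0)

  g <- matrix(42, 64, 64)
  m2 <- estimate_bleed(r, g, mask, cfg)
  expect_equal(m2$alpha, 0)
  expect_equal(m2$intercept, 42)

  expect_error(estimate_bleed(r, r, matrix(FALSE, 64, 64), cfg),
               class = "mcsc_insufficient_data")
  expect_error(estimate_bleed(matrix(5, 64, 64), r, mask, cfg),
               class = "mcsc_degenerate_fit")
})

test_that("bleed coefficient is recovered from a noisy synthetic field", {
  p <- small_params(bleed_alpha = 0.3, mcsc_rate = 0, seed = 21L)
  sim <- generate_wholemount(p)
  fol <- detect_follicles(sim$field$red)
  brush <- EBImage::makeBrush(7L, "disc")
  mask <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(fol$mask * 1), brush)) > 0
  fit <- estimate_bleed(sim$field$red, sim$field$green, mask)
  expect_lt(abs(fit$alpha - 0.3), 0.02)
  expect_lt(abs(fit$intercept - p$bg_level), 5)
})

test_that("unmixing obeys its algebraic identities", {
  r <- matrix(runif(32 * 32, 0, 100), 32, 32)
  g <- 0.3 * r + 5
  expect_equal(unmix_green(g, r, list(alpha = 0.3, intercept = 5)),
               matrix(0, 32, 32))
  expect_equal(unmix_green(g, r, list(alpha = 0, intercept = 0)), g)
  expect_error(unmix_green(g, r[1:16, ], list(alpha = 0, intercept = 0)),
               class = "mcsc_validation_error")

  # noise-free field: the true model recovers the pure spot image exactly
  p <- small_params(noise_sd = 0, mcsc_rate = 2, seed = 2L)
  sim <- generate_wholemount(p)
  corrected <- unmix_green(sim$field$green, sim$field$red,
                           list(alpha = p$bleed_alpha, intercept = p$bg_level))
  spot_img <- mcscquant:::.render_spots(p$height_px, p$width_px,
                                        sim$truth$mcsc_positions$x,
                                        sim$truth$mcsc_positions$y,
                                        p$spot_sigma_px, sim$truth$mcsc_peaks)
  expect_equal(max(abs(corrected - spot_img)), 0)
})

test_that("noise-free spots are counted exactly and localised within 1 px", {
  p <- small_params(noise_sd = 0, mcsc_rate = 2, seed = 2L)  # 48 spots
  sim <- generate_wholemount(p)
  corrected <- unmix_green(sim$field$green, sim$field$red,
                           list(alpha = p$bleed_alpha, intercept = p$bg_level))
  sp <- detect_mcsc_spots(corrected)
  truth <- sim$truth$mcsc_positions
  expect_equal(sp$count, nrow(truth))
  m <- mcscquant:::match_points(sp$centroids, truth, max_dist = 3)
  expect_equal(nrow(m), nrow(truth))
  expect_lte(max(m$dist), 1)
})

test_that("maxima closer than the suppression radius merge to one spot", {
  near <- two_spot_image(64, c(30, 30), c(33, 30))   # 3 px = 0.5 * min_sep
  far <- two_spot_image(64, c(20, 20), c(40, 40))
  expect_equal(detect_mcsc_spots(near)$count, 1)
  expect_equal(detect_mcsc_spots(far)$count, 2)
})

test_that("counts are invariant to global rescaling of both channels", {
  p <- small_params(mcsc_rate = 0.5, seed = 13L)
  sim <- generate_wholemount(p)
  q1 <- quantify_field(sim$field)
  f2 <- sim$field
  f2$green <- f2$green * 3.7
  f2$red <- f2$red * 3.7
  q2 <- quantify_field(f2)
  expect_equal(q2$record$n_follicles, q1$record$n_follicles)
  expect_equal(q2$record$n_mcsc, q1$record$n_mcsc)
  expect_equal(q2$record$alpha, q1$record$alpha, tolerance = 1e-8)
})

test_that("detected spot counts increase with the true melanocyte rate", {
  means <- vapply(c(0.02, 0.05, 0.1, 0.2), function(r) {
    mean(vapply(1:40, function(s) {
      p <- small_params(mcsc_rate = r, seed = 1000 * round(100 * r) + s)
      quantify_field(generate_wholemount(p)$field)$record$n_mcsc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("an all-zero field quantifies to zero counts with a flag", {
  f <- structure(list(green = matrix(0, 64, 64), red = matrix(0, 64, 64),
                      pixel_size_um = 1, field_id = "z", mouse_id = "z"),
                 class = "TwoChannelField")
  q <- quantify_field(f)
  expect_equal(q$record$n_follicles, 0)
  expect_equal(q$record$n_mcsc, 0)
  expect_match(q$record$flags, "low_contrast")
})

test_that("spot detection stays near-silent when no melanocytes exist", {
  fp <- vapply(1:10, function(s) {
    p <- small_params(mcsc_rate = 0, seed = 400 + s)
    quantify_field(generate_wholemount(p)$field)$record$n_mcsc
  }, numeric(1))
  expect_lte(mean(fp), 1)
})
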