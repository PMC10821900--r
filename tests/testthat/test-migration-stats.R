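test_that("per-mouse aggregation pools counts per the rate formula", {
  rec <- data.frame(mouse_id = "m1", n_follicles = c(320, 320),
                    n_mcsc = c(10, 6))
  mm <- aggregate_mouse(rec)
  expect_equal(mm$migration_rate, 16 / 640)
  expect_equal(mm$total_follicles, 640)
  expect_true("below_quantification_floor" %in% mm$flags)

  one <- aggregate_mouse(data.frame(mouse_id = "m1", n_follicles = 320,
                                    n_mcsc = 0))
  expect_equal(one$migration_rate, 0)

  big <- aggregate_mouse(data.frame(mouse_id = "m1",
                                    n_follicles = rep(320, 20),
                                    n_mcsc = rep(8, 20)))
  expect_false("below_quantification_floor" %in% big$flags)

  expect_error(aggregate_mouse(data.frame(mouse_id = c("m1", "m2"),
                                          n_follicles = c(10, 10),
                                          n_mcsc = c(1, 1))),
               class = "mcsc_validation_error")
  expect_error(aggregate_mouse(data.frame(mouse_id = "m1", n_follicles = 0,
                                          n_mcsc = 0)),
               class = "mcsc_validation_error")
})

test_that("pooled rate equals the follicle-weighted mean of field rates", {
  withr::with_seed(17L, {
    for (i in 1:20) {
      k <- sample(2:30, 1)
      rec <- data.frame(mouse_id = "m", n_follicles = sample(50:400, k, TRUE),
                        n_mcsc = rpois(k, 10))
      pooled <- aggregate_mouse(rec)$migration_rate
      w <- rec$n_follicles / sum(rec$n_follicles)
      expect_equal(pooled, sum(w * rec$n_mcsc / rec$n_follicles))
      # scale invariance in the counts
      rec2 <- rec; rec2$n_follicles <- rec$n_follicles * 3
      rec2$n_mcsc <- rec$n_mcsc * 3
      expect_equal(aggregate_mouse(rec2)$migration_rate, pooled)
    }
  })
})

test_that("normalization divides by the chosen per-mouse normalizer", {
  expect_equal(normalize_migration(0.02, 0.01, "littermate_control")$normalized_rate, 2)

  rec <- data.frame(mouse_id = "m1", n_follicles = 6400, n_mcsc = 160)
  mm <- aggregate_mouse(rec)
  self <- normalize_migration(mm, mm$migration_rate, "littermate_control")
  expect_equal(self$normalized_rate, 1)
  expect_equal(self$scheme, "littermate_control")

  # Cox-2 scheme composed with a section-quantification area ratio
  sp <- generate_section_pair(300, 300, 0.2, 0.4, noise_sd = 0, seed = 9)
  ar <- area_ratio(sp$stain, sp$dapi)
  nm <- normalize_migration(mm, ar$ratio, "cox2")
  expect_equal(nm$normalized_rate, mm$migration_rate / 0.5)

  expect_error(normalize_migration(0.1, 0, "cox2"),
               class = "mcsc_validation_error")
})

test_that("identical groups give t = 0, p = 1 under Welch", {
  a <- c(0.1, 0.25, 0.3, 0.18)
  gc <- compare_groups(a, a, "welch_t")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)
  expect_equal(gc$group_sems, rep(sd(a) / 2, 2))
})

test_that("zero-variance paired differences flag instead of fabricating p", {
  gc <- compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5), "paired_t")
  expect_true("degenerate_variance" %in% gc$flags)
  expect_true(is.na(gc$p_value))
  expect_equal(gc$group_means, c(2.5, 3.5))
})

test_that("Welch results match the closed-form oracle to 1e-10", {
  gc <- compare_groups(c(0.1, 0.2, 0.15), c(0.3, 0.35, 0.4), "welch_t")
  or <- welch_oracle(c(0.1, 0.2, 0.15), c(0.3, 0.35, 0.4))
  expect_equal(gc$statistic, or$statistic, tolerance = 1e-12)
  expect_equal(gc$p_value, or$p, tolerance = 1e-12)

  withr::with_seed(23L, {
    for (i in 1:100) {
      a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
      b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
      gc <- compare_groups(a, b, "welch_t")
      or <- welch_oracle(a, b)
      expect_lt(abs(gc$p_value - or$p), 1e-10)
      expect_lt(abs(gc$statistic - or$statistic), 1e-10)
    }
  })
})

test_that("exact Mann-Whitney p matches full enumeration for small groups", {
  withr::with_seed(29L, {
    for (i in 1:30) {
      a <- round(runif(sample(3:6, 1), 0, 100), 3)
      b <- round(runif(sample(3:6, 1), 0, 100), 3)
      if (anyDuplicated(c(a, b))) next
      gc <- compare_groups(a, b, "mann_whitney")
      or <- mw_enum_oracle(a, b)
      expect_equal(gc$statistic, or$u)
      expect_equal(gc$p_value, or$p, tolerance = 1e-12)
    }
  })
})

test_that("swapping groups negates the statistic and preserves p", {
  withr::with_seed(37L, {
    for (i in 1:10) {
      a <- rnorm(5); b <- rnorm(5, 0.5)
      for (tst in c("welch_t", "paired_t")) {
        g1 <- compare_groups(a, b, tst)
        g2 <- compare_groups(b, a, tst)
        expect_equal(g1$statistic, -g2$statistic)
        expect_equal(g1$p_value, g2$p_value)
      }
      m1 <- compare_groups(a, b, "mann_whitney")
      m2 <- compare_groups(b, a, "mann_whitney")
      expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
    }
  })
})

test_that("group-size and pairing contracts are enforced", {
  expect_error(compare_groups(1:5, 3, "welch_t"),
               class = "mcsc_insufficient_data")
  expect_error(compare_groups(c(1, 2, 3), c(1, 2), "paired_t"),
               class = "mcsc_validation_error")
  # paired ids realign the second group
  a <- c(1, 2, 3); b_shuffled <- c(30, 10, 20)
  gc <- compare_groups(a, b_shuffled, "paired_t",
                       paired_ids = list(a = c("x", "y", "z"),
                                         b = c("z", "x", "y")))
  gc2 <- compare_groups(a, c(10, 20, 30), "paired_t")
  expect_equal(gc$statistic, gc2$statistic)
})
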