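test_that("probability maps threshold at the stated fraction of their maximum", {
  expect_equal(as.numeric(threshold_probability_map(c(0.1, 0.5, 0.9, 1.0), 0.8)),
               c(0, 0, 1, 1))
  prob <- matrix(c(0.2, 0.4, 0.8, 1.0), 2)
  expect_equal(threshold_probability_map(prob),
               matrix(c(0L, 0L, 1L, 1L), 2))
  # a constant map keeps every voxel
  expect_true(all(threshold_probability_map(matrix(0.3, 3, 3)) == 1))
  expect_error(threshold_probability_map(matrix(0, 2, 2)), "positive")
  expect_error(threshold_probability_map(matrix(-1, 2, 2)), "non-negative")
})

test_that("MAPE reproduces hand values and is scale-invariant", {
  expect_equal(mape(1000, 1000), 0)
  expect_equal(mape(1000, 970), 3)
  expect_equal(mape(c(100, 200), c(90, 220)), 10)
  withr::with_seed(2, {
    r <- runif(50, 10, 100); p <- r * runif(50, 0.8, 1.2)
    expect_equal(mape(r, p), mape(7.3 * r, 7.3 * p), tolerance = 1e-12)
  })
  expect_error(mape(c(0, 1), c(1, 1)), "positive")
  expect_error(mape(1:3, 1:2), "differ")
})

test_that("ICC(A,1) matches mean-squares oracles and its limits", {
  # 4 hand-picked pairs, frozen against an independent mean-squares computation
  expect_equal(icc_agreement(c(1, 2, 3, 4), c(1.1, 2.3, 2.9, 4.2)),
               0.98876404, tolerance = 1e-7)
  expect_equal(icc_agreement(c(10, 12, 9, 15, 11), c(11, 14, 10, 14.5, 12.5)),
               0.82653061, tolerance = 1e-7)
  # perfect agreement
  withr::with_seed(3, x <- rnorm(30, 100, 10))
  expect_equal(icc_agreement(x, x), 1)
  # an uncorrelated permutation has ICC near 0 at large n
  withr::with_seed(4, {
    z <- rnorm(2000)
    expect_lt(abs(icc_agreement(z, sample(z))), 0.1)
  })
  expect_error(icc_agreement(1:2, 1:2), "3 pairs")
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "variance")
})

test_that("Bland-Altman agrees with hand-computed pairs", {
  ba <- bland_altman(c(100, 200, 300), c(110, 190, 300))
  expect_equal(ba$data$mean, c(105, 195, 300))
  expect_equal(ba$data$diff, c(-10, 10, 0))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$mean_diff, mean(c(100, 200, 300)) - mean(c(110, 190, 300)))

  # constant offset: mean_diff = -5, zero spread, degenerate correlation
  ba2 <- bland_altman(c(100, 200, 300), c(105, 205, 305))
  expect_equal(ba2$mean_diff, -5)
  expect_equal(ba2$diff_sd, 0)
  expect_true(ba2$degenerate)
  expect_true(is.na(ba2$pearson_r))

  # identical series are degenerate, not an error
  ba3 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_true(ba3$degenerate)

  # mean_diff always equals mean(x) - mean(y)
  withr::with_seed(5, {
    x <- rnorm(40, 50, 5); y <- rnorm(40, 48, 5)
    expect_equal(bland_altman(x, y)$mean_diff, mean(x) - mean(y), tolerance = 1e-12)
  })
})

test_that("map evaluation reports per-tissue agreement rows", {
  withr::with_seed(6, {
    t1 <- matrix(runif(64, 800, 1200), 8)
    t2s <- matrix(runif(64, 40, 90), 8)
  })
  ref <- parametric_maps(t1, t2s)
  masks <- list(GM = matrix(rep(c(1L, 0L), each = 32), 8),
                WM = matrix(rep(c(0L, 1L), each = 32), 8))

  # identical maps: zero error, full agreement
  rep0 <- evaluate_maps(ref, ref, masks)
  expect_s3_class(rep0, "mrf_eval")
  expect_equal(nrow(rep0), length(masks) * 2)
  expect_true(all(rep0$mape_pct == 0))
  expect_true(all(rep0$icc == 1))

  # hand-checked 4-voxel tissue
  small_mask <- matrix(0L, 8, 8); small_mask[1:4] <- 1L
  pred <- ref
  pred$t1_map[1:4] <- ref$t1_map[1:4] * c(1.1, 0.9, 1, 1.05)
  r <- evaluate_maps(ref, pred, list(roi = small_mask))
  row_t1 <- r[r$parameter == "T1", ]
  expect_equal(row_t1$n_voxels, 4)
  expect_equal(row_t1$mape_pct, 100 * mean(c(0.1, 0.1, 0, 0.05)), tolerance = 1e-12)
  expect_equal(row_t1$mean_diff_ms,
               mean(ref$t1_map[1:4] - pred$t1_map[1:4]), tolerance = 1e-12)

  expect_error(evaluate_maps(ref, pred, list(empty = matrix(0L, 8, 8))), "enough")
})

test_that("evaluation objects tidy, glance and plot", {
  withr::with_seed(7, {
    t1 <- matrix(runif(36, 800, 1200), 6)
    t2s <- matrix(runif(36, 40, 90), 6)
    pred <- parametric_maps(t1 * runif(36, 0.95, 1.05), t2s * runif(36, 0.95, 1.05))
  })
  ref <- parametric_maps(t1, t2s)
  rep1 <- evaluate_maps(ref, pred, list(brain = matrix(1L, 6, 6)))
  td <- tidy(rep1)
  expect_false(inherits(td, "mrf_eval"))
  gl <- glance(rep1)
  expect_true(all(c("parameter", "mean_mape_pct") %in% names(gl)))
  expect_s3_class(autoplot(rep1), "ggplot")
  ba <- bland_altman(as.numeric(t1), as.numeric(pred$t1_map))
  expect_s3_class(autoplot(ba), "ggplot")
  expect_s3_class(plot_map(ref, "t1"), "ggplot")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_csv(rep1, csv)
  expect_equal(nrow(read.csv(csv)), nrow(rep1))
})
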