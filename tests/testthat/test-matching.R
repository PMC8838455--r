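test_that("matching a dictionary row to itself returns that row with score 1", {
  dict <- fix_tiny_dictionary()
  for (j in c(1L, 10L, nrow(dict$params))) {
    m <- match_signal(dict$signals[j, ], dict)
    expect_equal(m$index, j)
    expect_equal(m$score, 1, tolerance = 1e-12)
    expect_equal(m$t1_ms, dict$params$t1_ms[j])
  }
  # scale invariance of the query
  m10 <- match_signal(10 * dict$signals[5, ], dict)
  expect_equal(m10$index, 5L)
  expect_equal(m10$score, 1, tolerance = 1e-12)
})

test_that("matching agrees with hand-computed dot products on a 3-entry toy", {
  dict <- fix_tiny_dictionary()
  toy <- dict
  toy$signals <- rbind(c(1, 0), c(0, 1), c(0.6, 0.8))
  toy$params <- tibble::tibble(t1_ms = 1:3, t2s_ms = 1:3, b1 = 1,
                               t1_idx = 1:3, t2s_idx = 1:3)
  q <- c(1, 1) / sqrt(2)
  m <- match_signal(q, toy)
  expect_equal(m$index, 3L)
  expect_equal(m$score, sum(q * c(0.6, 0.8)), tolerance = 1e-12)
  expect_equal(sum(q * c(0.6, 0.8)), 0.98994949, tolerance = 1e-7)
})

test_that("match_signal equals a brute-force cosine argmax on random queries", {
  dict <- fix_tiny_dictionary()
  withr::with_seed(11, {
    for (i in 1:50) {
      q <- rnorm(35)
      m <- match_signal(q, dict)
      cosims <- dict$signals %*% (q / sqrt(sum(q^2)))
      expect_equal(m$index, which.max(cosims))
      expect_equal(m$score, max(cosims), tolerance = 1e-12)
    }
  })
})

test_that("zero-norm queries are flagged unmatched", {
  dict <- fix_tiny_dictionary()
  m <- match_signal(rep(0, 35), dict)
  expect_true(is.na(m$index))
  expect_true(is.na(m$score))
})

test_that("match_stack recovers generating entries exactly and fills masks", {
  dict <- fix_tiny_dictionary()
  withr::with_seed(3, idx <- sample.int(nrow(dict$params), 12))
  stack_data <- array(0, c(4, 3, 35))
  flat <- matrix(stack_data, 12, 35)
  flat[] <- dict$signals[idx, ]
  stack <- baseline_stack(array(t(flat), c(35, 4, 3)) |> aperm(c(2, 3, 1)))
  res <- match_stack(stack, dict)
  expect_equal(as.integer(res$index_map), idx)
  expect_equal(as.numeric(res$t1_map), dict$params$t1_ms[idx])
  expect_equal(as.numeric(res$t2s_map), dict$params$t2s_ms[idx])
  expect_equal(res$n_unmatched, 0L)

  # all-zero stack: every in-mask voxel unmatched, maps at the 0 sentinel
  zs <- baseline_stack(array(0, c(4, 3, 35)))
  rz <- match_stack(zs, dict)
  expect_equal(rz$n_unmatched, 12L)
  expect_true(all(rz$t1_map == 0))

  # masked-out voxels stay 0
  msk <- matrix(0L, 4, 3); msk[1, 1] <- 1L
  stack2 <- baseline_stack(stack$data, msk)
  r2 <- match_stack(stack2, dict)
  expect_equal(sum(r2$t1_map != 0), 1L)
})

test_that("SNR follows its closed forms", {
  expect_equal(compute_snr(c(3, 4), c(1, 0)), 10 * log10(25), tolerance = 1e-12)
  expect_equal(compute_snr(c(3, 4), c(1, 0)), 13.97940, tolerance = 1e-5)
  expect_equal(compute_snr(rep(1, 35), rep(0.1, 35)), 20)
  expect_identical(compute_snr(c(1, 2), c(0, 0)), Inf)
  expect_error(compute_snr(c(0, 0), c(1, 1)), "energy")
  # scaling the residual by 10 lowers SNR by exactly 20 dB
  withr::with_seed(4, {
    s <- rnorm(35); n <- rnorm(35, sd = 0.1)
    expect_equal(compute_snr(s, n) - compute_snr(s, 10 * n), 20, tolerance = 1e-12)
  })
})

test_that("noise bank extraction returns residuals, SNR map and bookkeeping", {
  dict <- fix_tiny_dictionary()
  withr::with_seed(5, idx <- sample.int(nrow(dict$params), 10))
  clean <- dict$signals[idx, ]
  stack <- baseline_stack(aperm(array(t(clean), c(35, 5, 2)), c(2, 3, 1)))
  nb <- extract_noise_bank(stack, dict)
  # noise-free stack: residual energy ~ 0, SNR at the +Inf sentinel
  expect_lt(max(abs(nb$bank$residuals)), 1e-9)
  expect_equal(length(nb$bank$pooled_values), 10 * 35)
  expect_true(all(nb$snr_map[stack$brain_mask == 1] > 100 |
                    is.infinite(nb$snr_map[stack$brain_mask == 1])))

  # known perturbation: residual equals the normalization-adjusted offset
  d <- c(0.05, rep(0, 34))
  one <- clean[1, ] + d
  stack1 <- baseline_stack(array(rep(one, each = 1), c(1, 1, 35)))
  nb1 <- extract_noise_bank(stack1, dict)
  want <- one / sqrt(sum(one^2)) - dict$signals[nb1$match$index_map[1, 1], ]
  expect_equal(as.numeric(nb1$bank$residuals[1, ]), want, tolerance = 1e-12)
})

test_that("noise sampling is seeded, order-free and mode-correct", {
  bank <- fix_gaussian_bank(n = 50)
  a <- sample_noise(bank, 35, seed = 9)
  b <- sample_noise(bank, 35, seed = 9)
  expect_identical(a, b)
  expect_true(all(a %in% bank$pooled_values))

  # degenerate single-value pool
  bank1 <- bank
  bank1$pooled_values <- 0.42
  expect_equal(sample_noise(bank1, 35, seed = 1), rep(0.42, 35))

  # permuted_vector preserves the multiset of one stored row
  bank2 <- bank
  bank2$residuals <- bank$residuals[1, , drop = FALSE]
  p <- sample_noise(bank2, 35, mode = "permuted_vector", seed = 2)
  expect_equal(sort(p), sort(bank2$residuals[1, ]))

  empty <- bank
  empty$pooled_values <- numeric(0)
  expect_error(sample_noise(empty, 35), "empty")
})

test_that("sampled noise round-trips through extraction with matched energy", {
  # T2*-only dictionary: neighbouring entries are well separated, so faint
  # (60 dB) noise cannot flip the best match
  dict <- generate_dictionary(
    make_schedule(),
    grid_spec(1000, 1100, 50, 90, 0.08, b1_min = 1, b1_max = 1, b1_step = 0.1)
  )
  bank <- fix_gaussian_bank(snr_db = 60, n = 100)
  withr::with_seed(8, j <- sample.int(nrow(dict$params), 1))
  eps <- sample_noise(bank, 35, seed = 21)
  noisy <- dict$signals[j, ] + eps
  stack <- baseline_stack(array(noisy, c(1, 1, 35)))
  nb <- extract_noise_bank(stack, dict)
  expect_equal(nb$match$index_map[1, 1], j)
  renorm <- noisy / sqrt(sum(noisy^2)) - dict$signals[j, ]
  expect_equal(sum(nb$bank$residuals^2), sum(renorm^2), tolerance = 1e-6)
})

test_that("noise banks round-trip through the HDF5 container", {
  bank <- fix_gaussian_bank(n = 20)
  path <- withr::local_tempfile(fileext = ".h5")
  write_noise_bank(bank, path)
  back <- read_noise_bank(path)
  expect_equal(back$residuals, bank$residuals, ignore_attr = TRUE)
  expect_equal(back$pooled_values, bank$pooled_values)
  expect_equal(back$source_meta, bank$source_meta)
})
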