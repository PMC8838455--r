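test_that("the pyramid produces valid-convolution scale lengths 19/9/3", {
  spec <- regressor_spec()
  expect_equal(spec$scale_lengths, c(19L, 9L, 3L))
  expect_equal(spec$backbone_kernels, c(17L, 11L, 7L))
  expect_equal(spec$backbone_channels, c(128L, 256L, 512L))
  expect_error(regressor_spec(backbone_channels = c(100, 256, 512)), "divisible")
  expect_error(regressor_spec(n_timepoints = 10), "exceed")
})

test_that("every variant emits two finite outputs per fingerprint", {
  withr::with_seed(1, x <- matrix(abs(rnorm(3 * 35)), 3, 35))
  for (v in c("WPDaCNN", "PDCNN", "DCNN", "SCNN")) {
    m <- build_regressor(fix_regressor_spec(v), seed = 2)
    out <- predict_params(m, x)
    expect_equal(dim(out), c(3L, 2L))
    expect_true(all(is.finite(out)))
  }
  # SCNN is a single path whose final layer emits both values
  scnn <- build_regressor(fix_regressor_spec("SCNN"), seed = 2)
  expect_length(scnn$params$path, 1L)
  expect_equal(nrow(scnn$params$path[[1]]$out$w), 2L)
  # dual-path variants carry one output unit per path
  wp <- build_regressor(fix_regressor_spec("WPDaCNN"), seed = 2)
  expect_length(wp$params$path, 2L)
  expect_equal(nrow(wp$params$path[[1]]$out$w), 1L)
})

test_that("stage-II loss reproduces its hand-computed values", {
  expect_equal(stage2_loss(c(1000, 50), c(1000, 50)), 0)
  expect_equal(stage2_loss(1000, 990), 11)             # 10 + 100 * 0.01
  expect_equal(stage2_loss(c(1000, 50), c(1000, 45)), 7.5)
  expect_error(stage2_loss(c(0, 50), c(1, 45)), "positive")
})

test_that("with zero attention gammas the WPDaCNN equals a weight-matched PDCNN", {
  wspec <- regressor_spec(backbone_channels = c(16L, 24L, 32L),
                          n_heads = 8L, head_hidden = 10L)
  pspec <- regressor_spec(backbone_channels = c(16L, 24L, 32L),
                          n_heads = 8L, head_hidden = 10L, variant = "PDCNN")
  wm <- build_regressor(wspec, seed = 9)
  pm <- build_regressor(pspec, seed = 10)
  # copy shared weights; gamma_attn stays at its 0 init, set scale weights to 1
  pm$params$backbone <- wm$params$backbone
  for (p in 1:2) {
    wm$params$path[[p]]$gamma_scale <- rep(1, 3)
    for (s in 1:3) {
      pm$params$path[[p]]$scale[[s]]$fc1 <- wm$params$path[[p]]$scale[[s]]$fc1
      pm$params$path[[p]]$scale[[s]]$fc2 <- wm$params$path[[p]]$scale[[s]]$fc2
    }
    pm$params$path[[p]]$out <- wm$params$path[[p]]$out
  }
  withr::with_seed(3, x <- matrix(abs(rnorm(4 * 35)), 4, 35))
  expect_equal(predict_params(wm, x), predict_params(pm, x), tolerance = 1e-12)
})

test_that("inference is deterministic: dropout only acts during training", {
  m <- build_regressor(fix_regressor_spec(), seed = 5)
  withr::with_seed(8, x <- matrix(abs(rnorm(2 * 35)), 2, 35))
  expect_identical(predict_params(m, x), predict_params(m, x))
  # but dropout does perturb the training-mode forward pass
  set.seed(1)
  f1 <- mrfepi:::regressor_forward(m, x, training = TRUE)$out
  set.seed(2)
  f2 <- mrfepi:::regressor_forward(m, x, training = TRUE)$out
  expect_false(identical(f1, f2))
})

test_that("a one-epoch training run returns a checkpoint with seeded curves", {
  dict <- fix_tiny_dictionary()
  split <- split_by_increment(dict, 2L)
  spec <- regressor_spec(backbone_channels = c(8L, 8L, 16L), n_heads = 4L,
                         head_hidden = 8L)
  cfg <- stage2_config(batch_size = 16, epochs = 1, seed = 31)
  m1 <- train_regressor(dict, split, spec, cfg)
  expect_true(m1$trained)
  expect_equal(m1$best_epoch, 1)
  expect_setequal(unique(m1$history$set), c("train", "valid"))
  expect_true(all(c("l1_ms", "mape_pct") %in% names(m1$history)))
  m2 <- train_regressor(dict, split, spec, cfg)
  expect_identical(m1$history, m2$history)
  withr::with_seed(2, x <- matrix(abs(rnorm(2 * 35)), 2, 35))
  expect_identical(predict_params(m1, x), predict_params(m2, x))
})

test_that("the whitening input layer is fixed, invertible-scaled and capped", {
  dict <- fix_tiny_dictionary()
  tf <- mrfepi:::compute_whitening(dict$signals, gain_cap = 100)
  xw <- mrfepi:::apply_input_transform(dict$signals, tf)
  # whitened training data has near-unit variance in its leading directions
  v <- eigen(stats::cov(xw), symmetric = TRUE)$values
  expect_lt(max(v), 1 + 1e-6)
  # gain cap bounds the operator norm of W relative to the data scale
  lmax <- max(eigen(stats::cov(dict$signals), symmetric = TRUE)$values)
  wnorm <- max(svd(tf$W)$d)
  expect_lte(wnorm, 100 / sqrt(lmax) * (1 + 1e-9))
})

test_that("two-stage prediction honors the mask and output contract", {
  dict <- fix_tiny_dictionary()
  split <- split_by_increment(dict, 2L)
  reg <- train_regressor(dict, split,
                         regressor_spec(backbone_channels = c(8L, 8L, 16L),
                                        n_heads = 4L, head_hidden = 8L),
                         stage2_config(batch_size = 16, epochs = 1, seed = 3))
  withr::with_seed(4, idx <- sample.int(nrow(dict$params), 6))
  flat <- dict$signals[idx, ]
  stack_arr <- aperm(array(t(flat), c(35, 3, 2)), c(2, 3, 1))
  mask <- matrix(1L, 3, 2); mask[3, 2] <- 0L
  stack <- baseline_stack(stack_arr, mask)
  maps <- predict_two_stage(NULL, reg, stack)
  expect_s3_class(maps, "mrf_maps")
  expect_equal(dim(maps$t1_map), c(3L, 2L))
  expect_equal(maps$t1_map[3, 2], 0)
  expect_equal(maps$t2s_map[3, 2], 0)
  expect_true(all(maps$t1_map[mask == 1] > 0))

  # denoiser in front: same contract
  bank <- fix_gaussian_bank(n = 50)
  den <- train_denoiser(dict, bank, stage1_config(batch_size = 42, epochs = 1, seed = 2),
                        denoiser_spec(depth_middle = 1, channels = 4), quiet = TRUE)
  maps2 <- predict_two_stage(den, reg, stack)
  expect_equal(maps2$t1_map[3, 2], 0)
  expect_true(all(is.finite(maps2$t1_map)))
})
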