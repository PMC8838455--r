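test_that("denoiser spec validates and the network has the stated layer count", {
  spec <- denoiser_spec()
  expect_equal(spec$depth_middle, 32L)
  expect_equal(spec$channels, 64L)
  model <- build_denoiser(spec, seed = 1)
  # conv layers: first + 32 middle + last = 34, counted off the built graph
  expect_equal(mrfepi:::denoiser_n_conv_layers(model), 34L)
  expect_error(denoiser_spec(kernel = 4), "odd")
  expect_error(denoiser_spec(padding = 0), "preserve")
  expect_error(denoiser_spec(depth_middle = 0), ">= 1")
})

test_that("the denoiser preserves signal length for any input length", {
  model <- build_denoiser(denoiser_spec(depth_middle = 2, channels = 4), seed = 2)
  for (len in c(3, 16, 35, 60)) {
    x <- matrix(rnorm(2 * len), 2, len)
    expect_equal(dim(mrfepi:::denoiser_forward(model, x)$out), c(2L, len))
  }
  expect_error(denoise_signal(model, rnorm(2)), "kernel")
})

test_that("a zero-weight denoiser predicts zero noise and passes inputs through", {
  model <- build_denoiser(denoiser_spec(depth_middle = 2, channels = 4), seed = 3)
  flat <- mrfepi:::flatten_params(model$params)
  flat <- lapply(flat, function(p) p * 0)
  model$params <- mrfepi:::unflatten_params(flat, model$params)
  x <- matrix(rnorm(3 * 35), 3, 35)
  expect_equal(mrfepi:::denoiser_forward(model, x)$out, x * 0)
  expect_equal(denoise_signal(model, x), x)
})

test_that("denoising obeys the residual-learning identity", {
  model <- build_denoiser(denoiser_spec(depth_middle = 2, channels = 8), seed = 4)
  x <- matrix(rnorm(5 * 35), 5, 35)
  # output = input - predicted residual, so the two calls are mutually exact
  expect_identical(denoise_signal(model, x), x - predict_residual(model, x))
  expect_equal(denoise_signal(model, x) + predict_residual(model, x), x,
               tolerance = 1e-12)
  # vector in, vector out
  v <- rnorm(35)
  expect_length(denoise_signal(model, v), 35)
})

test_that("stage-I loss reproduces its hand-computed values", {
  expect_equal(stage1_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(stage1_loss(0.01, 0), 1)
  # batch of two length-2 pairs, differences (0.01, 0.02, 0, 0.01)
  expect_equal(stage1_loss(c(0.01, 0.02, 0, 0.01), c(0, 0, 0, 0)), 1.5)
  expect_error(stage1_loss(1:3, 1:2), "differ")
})

test_that("one-epoch training returns a checkpoint, a loss log, and is seeded", {
  dict <- fix_tiny_dictionary()
  bank <- fix_gaussian_bank(n = 100)
  cfg <- stage1_config(batch_size = 20, epochs = 1, seed = 42)
  spec <- denoiser_spec(depth_middle = 2, channels = 8)
  m1 <- train_denoiser(dict, bank, cfg, spec, quiet = TRUE)
  expect_true(m1$trained)
  expect_equal(nrow(m1$history), 1)
  expect_equal(m1$best_epoch, 1)
  m2 <- train_denoiser(dict, bank, cfg, spec, quiet = TRUE)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(mrfepi:::flatten_params(m1$params),
                   mrfepi:::flatten_params(m2$params))
  # model selection without a validation split is warned about
  expect_warning(train_denoiser(dict, bank, cfg, spec), "training")
})

test_that("fixed-corruption mode differs from fresh resampling", {
  dict <- fix_tiny_dictionary()
  bank <- fix_gaussian_bank(n = 100)
  spec <- denoiser_spec(depth_middle = 1, channels = 4)
  fresh <- train_denoiser(dict, bank,
                          stage1_config(batch_size = 42, epochs = 2, seed = 7),
                          spec, quiet = TRUE)
  fixed <- train_denoiser(dict, bank,
                          stage1_config(batch_size = 42, epochs = 2, seed = 7,
                                        resample_noise = FALSE),
                          spec, quiet = TRUE)
  expect_false(identical(fresh$history$loss, fixed$history$loss))
})

test_that("denoiser checkpoints round-trip through the HDF5 archive", {
  dict <- fix_tiny_dictionary()
  bank <- fix_gaussian_bank(n = 50)
  m <- train_denoiser(dict, bank, stage1_config(batch_size = 42, epochs = 1, seed = 3),
                      denoiser_spec(depth_middle = 2, channels = 6), quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".h5")
  write_denoiser(m, path)
  back <- read_denoiser(path)
  x <- matrix(rnorm(4 * 35), 4, 35)
  expect_equal(denoise_signal(back, x), denoise_signal(m, x), tolerance = 1e-12)
})

test_that("an affine-oracle denoiser bounds what stage I can achieve", {
  # ridge-solved affine map from noisy signal to noise: the best linear
  # denoiser. On this nearly flat 2-parameter signal manifold it gains
  # 15-17 dB at 20 dB input, an upper reference for the trained CNN.
  dict <- fix_dictionary()
  withr::with_seed(61, idx <- sample.int(nrow(dict$params), 2000))
  clean <- dict$signals[idx, ]
  en <- 10^(-20 / 10)
  withr::with_seed(62, n <- matrix(rnorm(length(clean), sd = sqrt(en / 35)),
                                   nrow(clean), 35))
  x <- cbind(1, clean + n)
  w <- solve(crossprod(x) + diag(1e-8, 36), crossprod(x, n))
  withr::with_seed(64, ho <- sample(setdiff(seq_len(nrow(dict$params)), idx), 200))
  hc <- dict$signals[ho, ]
  withr::with_seed(63, hn <- matrix(rnorm(length(hc), sd = sqrt(en / 35)),
                                    200, 35))
  deno <- (hc + hn) - cbind(1, hc + hn) %*% w
  gain <- mean(vapply(1:200, function(i) {
    compute_snr(hc[i, ], deno[i, ] - hc[i, ]) - compute_snr(hc[i, ], hn[i, ])
  }, numeric(1)))
  expect_gt(gain, 15)
})
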