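#' Stage-I denoiser specification (1D DnCNN)
#'
#' Residual-learning denoiser for fingerprints: the network predicts the
#' noise component of its input, and the clean signal is recovered by
#' subtraction. Architecture: `conv(k, pad, channels) + ReLU`, then
#' `depth_middle` units of `conv + batch-norm + ReLU`, then a final `conv`
#' down to one channel. Kernel 3 with padding 1 preserves the signal length.
#'
#' @param depth_middle Number of middle conv+BN+ReLU units (reference
#'   architecture: 32).
#' @param channels Channels in the hidden convolutions (reference: 64).
#' @param kernel Odd kernel size (default 3).
#' @param padding Padding per side; must equal `(kernel - 1) / 2` so the
#'   length is preserved.
#' @param n_timepoints Fingerprint length (default 35).
#' @return Object of class `mrf_denoiser_spec`.
#' @export
denoiser_spec <- function(depth_middle = 32L, channels = 64L, kernel = 3L,
                          padding = 1L, n_timepoints = 35L) {
  depth_middle <- as.integer(depth_middle)
  if (depth_middle < 1L) abort("`depth_middle` must be >= 1.")
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) abort("`kernel` must be odd.")
  if (as.integer(padding) != (kernel - 1L) %/% 2L) {
    abort("`padding` must equal (kernel - 1) / 2 to preserve signal length.")
  }
  structure(
    list(depth_middle = depth_middle, channels = as.integer(channels),
         kernel = kernel, padding = as.integer(padding),
         n_timepoints = as.integer(n_timepoints)),
    class = "mrf_denoiser_spec"
  )
}

#' Build an untrained stage-I denoiser
#'
#' @param spec An `mrf_denoiser_spec`.
#' @param seed Integer seed for the (Kaiming) weight initialization.
#' @return Object of class `mrf_denoiser` holding the spec, the weights and
#'   the batch-norm running statistics.
#' @export
build_denoiser <- function(spec = denoiser_spec(), seed = 1L) {
  stopifnot(inherits(spec, "mrf_denoiser_spec"))
  ch <- spec$channels; k <- spec$kernel
  with_seed(seed, {
    params <- list(
      first = list(w = init_conv(ch, 1L, k), b = numeric(ch)),
      # the head predicts small-amplitude residuals; a near-zero init starts
      # the network at the zero-prediction baseline instead of far above it
      last = list(w = init_conv(1L, ch, k) * 1e-3, b = numeric(1L))
    )
    params$mid <- lapply(seq_len(spec$depth_middle), function(i) {
      list(w = init_conv(ch, ch, k), b = numeric(ch),
           gamma = rep(1, ch), beta = numeric(ch))
    })
  })
  running <- lapply(seq_len(spec$depth_middle), function(i) {
    list(mean = numeric(ch), var = rep(1, ch))
  })
  structure(
    list(spec = spec, params = params, running = running, trained = FALSE),
    class = "mrf_denoiser"
  )
}

#' @export
print.mrf_denoiser <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<mrf_denoiser> DnCNN-1D: conv+ReLU, %d x [conv+BN+ReLU], conv; k=%d, %d channels%s\n",
    s$depth_middle, s$kernel, s$channels,
    if (isTRUE(x$trained)) " (trained)" else " (untrained)"
  ))
  invisible(x)
}

# count of convolution layers, used by structural tests
denoiser_n_conv_layers <- function(model) {
  2L + length(model$params$mid)
}

# forward pass; x: [B, T] matrix of noisy signals -> predicted residuals [B, T]
# training = TRUE uses batch statistics and returns caches for backward.
denoiser_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  B <- nrow(x); L <- ncol(x)
  a <- array(t(x), c(1L, L, B))
  caches <- list()

  cv <- conv1d_forward(a, model$params$first$w, model$params$first$b,
                       pad = spec$padding)
  rl <- relu_forward(cv$out)
  caches$first <- list(conv = cv$cache, relu = rl$cache)
  a <- rl$out

  caches$mid <- vector("list", length(model$params$mid))
  for (i in seq_along(model$params$mid)) {
    p <- model$params$mid[[i]]
    cv <- conv1d_forward(a, p$w, p$b, pad = spec$padding)
    bn <- bn_forward(cv$out, p$gamma, p$beta, model$running[[i]], training)
    if (training) model$running[[i]] <- bn$running
    rl <- relu_forward(bn$out)
    caches$mid[[i]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
    a <- rl$out
  }

  cv <- conv1d_forward(a, model$params$last$w, model$params$last$b,
                       pad = spec$padding)
  caches$last <- cv$cache
  list(out = t(matrix(cv$out, L, B)), caches = caches, model = model)
}

# backward pass from d(out) [B, T]; returns grads in the params structure
denoiser_backward <- function(model, caches, dout) {
  B <- nrow(dout); L <- ncol(dout)
  dy <- array(t(dout), c(1L, L, B))
  grads <- list(first = list(), last = list(), mid = vector("list", length(model$params$mid)))

  bk <- conv1d_backward(dy, caches$last)
  grads$last <- list(w = bk$dw, b = bk$db)
  dy <- bk$dx

  for (i in rev(seq_along(model$params$mid))) {
    cc <- caches$mid[[i]]
    dy <- relu_backward(dy, cc$relu)
    bnb <- bn_backward(dy, cc$bn)
    bk <- conv1d_backward(bnb$dx, cc$conv)
    grads$mid[[i]] <- list(w = bk$dw, b = bk$db,
                           gamma = bnb$dgamma, beta = bnb$dbeta)
    dy <- bk$dx
  }

  dy <- relu_backward(dy, caches$first$relu)
  bk <- conv1d_backward(dy, caches$first$conv)
  grads$first <- list(w = bk$dw, b = bk$db)
  grads
}

#' Stage-I training loss
#'
#' Scaled L2: `10000 x mean((true - predicted)^2)` over all values in the
#' batch. The scaling keeps the loss on a readable magnitude for the small
#' residual amplitudes of unit-norm fingerprints.
#'
#' @param true_residual,pred_residual Equal-shape numeric vectors/matrices.
#' @return Single number.
#' @export
stage1_loss <- function(true_residual, pred_residual) {
  if (length(true_residual) != length(pred_residual)) {
    abort("residual shapes differ.")
  }
  10000 * mean((as.numeric(true_residual) - as.numeric(pred_residual))^2)
}

#' Stage-I training configuration
#'
#' Reference settings: batch 500, Adam with learning rate 0.01 and a 5%
#' learning-rate reduction per epoch, 100 epochs, noise freshly sampled
#' from the bank every epoch.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_per_epoch Fractional LR reduction per epoch (0.05 = 5%).
#' @param epochs Training epochs.
#' @param noise_mode Residual sampling mode, see [sample_noise()].
#' @param resample_noise If `FALSE`, the corruption is drawn once and fixed
#'   across epochs (ablation mode).
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @return Object of class `mrf_stage1_config`.
#' @export
stage1_config <- function(batch_size = 500L, learning_rate = 0.01,
                          lr_decay_per_epoch = 0.05, epochs = 100L,
                          noise_mode = "pooled_iid", resample_noise = TRUE,
                          seed = 1L) {
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch >= 1) {
    abort("`lr_decay_per_epoch` must be in (0, 1).")
  }
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         lr_decay_per_epoch = lr_decay_per_epoch, epochs = as.integer(epochs),
         noise_mode = noise_mode, resample_noise = isTRUE(resample_noise),
         seed = as.integer(seed)),
    class = "mrf_stage1_config"
  )
}

#' Train the stage-I denoiser
#'
#' Every epoch, each dictionary fingerprint is corrupted with a freshly
#' sampled residual vector from the noise bank; the model input is the noisy
#' signal and the target is the residual itself (residual learning). The
#' checkpoint with the lowest epoch training loss is returned -- note this
#' selection uses the training error, with no validation split, which is
#' unconventional but deliberate for this stage; a warning records it.
#'
#' @param dict An `mrf_dictionary` providing the clean signals.
#' @param bank An `mrf_noise_bank`.
#' @param cfg An `mrf_stage1_config`.
#' @param spec An `mrf_denoiser_spec` (architecture).
#' @param entries Optional integer subset of dictionary rows to train on.
#' @param quiet Suppress the model-selection warning and progress messages.
#' @return A trained `mrf_denoiser` with a `history` tibble
#'   (`epoch`, `loss`, `lr`) and `best_epoch` attached.
#' @export
train_denoiser <- function(dict, bank, cfg = stage1_config(),
                           spec = denoiser_spec(), entries = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(dict, "mrf_dictionary"), inherits(bank, "mrf_noise_bank"),
            inherits(cfg, "mrf_stage1_config"))
  if (!quiet) {
    warn(paste("stage-I model selection uses the lowest *training* error;",
               "no validation split is held out."))
  }
  signals <- dict$signals
  if (!is.null(entries)) signals <- signals[entries, , drop = FALSE]
  n <- nrow(signals); nt <- ncol(signals)
  if (n == 0L) abort("no training signals.")

  model <- build_denoiser(spec, seed = derive_seed(cfg$seed, 1L))
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)

  best <- list(loss = Inf, params = NULL, running = NULL, epoch = NA_integer_)
  hist <- vector("list", cfg$epochs)
  lr <- cfg$learning_rate

  fixed_noise <- NULL
  with_seed(derive_seed(cfg$seed, 2L), {
    if (!cfg$resample_noise) {
      fixed_noise <- sample_noise_matrix(bank, nt, n, mode = cfg$noise_mode)
    }
    for (epoch in seq_len(cfg$epochs)) {
      noise <- if (cfg$resample_noise) {
        sample_noise_matrix(bank, nt, n, mode = cfg$noise_mode)
      } else fixed_noise
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        noisy <- signals[idx, , drop = FALSE] + noise[idx, , drop = FALSE]
        target <- noise[idx, , drop = FALSE]

        fw <- denoiser_forward(model, noisy, training = TRUE)
        model <- fw$model # updated BN running stats
        pred <- fw$out
        loss <- stage1_loss(target, pred)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss).", epoch))
        }
        dpred <- 10000 * 2 * (pred - target) / length(target)
        grads <- flatten_params(denoiser_backward(model, fw$caches, dpred))
        st <- adam_step(flat, grads, opt, lr)
        flat <- st$params; opt <- st$state
        model$params <- unflatten_params(flat, model$params)

        ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
      }
      ep_loss <- ep_loss / ep_n
      hist[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss, lr = lr)
      if (ep_loss < best$loss) {
        best <- list(loss = ep_loss, params = model$params,
                     running = model$running, epoch = epoch)
      }
      lr <- lr * (1 - cfg$lr_decay_per_epoch)
    }
  })

  model$params <- best$params
  model$running <- best$running
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$config <- cfg
  model
}

#' Denoise fingerprints with a trained stage-I model
#'
#' Residual learning: the model predicts the noise, which is subtracted from
#' the input. Inference uses the stored batch-norm running statistics, so
#' repeated calls are bit-identical.
#'
#' @param model An `mrf_denoiser`.
#' @param noisy A numeric vector (one fingerprint) or `B x T` matrix.
#' @return Denoised signal(s), same shape as the input.
#' @export
denoise_signal <- function(model, noisy) {
  stopifnot(inherits(model, "mrf_denoiser"))
  vec <- is.null(dim(noisy))
  x <- if (vec) matrix(noisy, 1L) else as.matrix(noisy)
  if (ncol(x) < model$spec$kernel) abort("input shorter than the kernel.")
  res <- denoiser_forward(model, x, training = FALSE)$out
  out <- x - res
  if (vec) drop(out) else out
}

#' Predict the noise component only
#' @inheritParams denoise_signal
#' @return Predicted residual(s), same shape as the input.
#' @export
predict_residual <- function(model, noisy) {
  stopifnot(inherits(model, "mrf_denoiser"))
  vec <- is.null(dim(noisy))
  x <- if (vec) matrix(noisy, 1L) else as.matrix(noisy)
  res <- denoiser_forward(model, x, training = FALSE)$out
  if (vec) drop(res) else res
}

#' Save / load a denoiser checkpoint (HDF5)
#' @param model An `mrf_denoiser`.
#' @param path `.h5` path.
#' @return `path` invisibly / an `mrf_denoiser`.
#' @export
write_denoiser <- function(model, path) {
  stopifnot(inherits(model, "mrf_denoiser"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  s <- model$spec
  rhdf5::h5write(c(s$depth_middle, s$channels, s$kernel, s$padding,
                   s$n_timepoints, as.numeric(isTRUE(model$trained))),
                 path, "spec")
  flat <- flatten_params(model$params)
  rhdf5::h5createGroup(path, "params")
  for (nm in names(flat)) {
    rhdf5::h5write(flat[[nm]], path, paste0("params/", gsub("\\.", "__", nm)))
  }
  rhdf5::h5createGroup(path, "running")
  for (i in seq_along(model$running)) {
    rhdf5::h5write(model$running[[i]]$mean, path, sprintf("running/mean%03d", i))
    rhdf5::h5write(model$running[[i]]$var, path, sprintf("running/var%03d", i))
  }
  if (!is.null(model$history)) {
    rhdf5::h5write(as.matrix(model$history), path, "history")
  }
  invisible(path)
}

#' @rdname write_denoiser
#' @export
read_denoiser <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  sp <- as.numeric(rhdf5::h5read(path, "spec"))
  spec <- denoiser_spec(sp[1], sp[2], sp[3], sp[4], sp[5])
  model <- build_denoiser(spec, seed = 0L)
  flat <- flatten_params(model$params)
  for (nm in names(flat)) {
    v <- rhdf5::h5read(path, paste0("params/", gsub("\\.", "__", nm)))
    flat[[nm]] <- if (is.null(dim(flat[[nm]]))) {
      as.numeric(v)
    } else {
      array(as.numeric(v), dim(flat[[nm]]))
    }
  }
  model$params <- unflatten_params(flat, model$params)
  for (i in seq_along(model$running)) {
    model$running[[i]]$mean <- as.numeric(rhdf5::h5read(path, sprintf("running/mean%03d", i)))
    model$running[[i]]$var <- as.numeric(rhdf5::h5read(path, sprintf("running/var%03d", i)))
  }
  model$trained <- sp[6] > 0
  model
}
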