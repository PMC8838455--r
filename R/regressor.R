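#' Stage-II regressor specification (WPDaCNN family)
#'
#' The stage-II model regresses T1 and T2* (ms) directly from a fingerprint.
#' A shared convolutional backbone of three blocks (`conv + ReLU + dropout`,
#' valid convolutions, stride 1) produces feature maps at three scales; for
#' a 35-point fingerprint with kernels 17/11/7 the scale lengths are 19, 9
#' and 3. Each output path (T1 and T2*) taps every scale through multi-head
#' self-attention gated by a learnable scalar gamma (initialized 0, so
#' attention starts as a no-op), flattens, and applies FC(`head_hidden`) +
#' ReLU + FC(`head_out`); the per-scale outputs are combined with learnable
#' scale weights (initialized 1/m) and a final FC emits the parameter value.
#'
#' Variants: `"WPDaCNN"` (full model), `"PDCNN"` (no attention, no gammas;
#' plain sum across scales), `"DCNN"` (PDCNN with only the third scale),
#' `"SCNN"` (DCNN with a single path whose final FC emits both values).
#'
#' @param backbone_kernels Length-3 integer kernel sizes (default 17, 11, 7).
#' @param backbone_channels Length-3 channel counts (default 128, 256, 512);
#'   each must be divisible by `n_heads`.
#' @param dropout_p Dropout probability in the backbone (default 0.2).
#' @param n_heads Attention heads (default 8).
#' @param head_hidden Hidden features of the per-scale head (default 128).
#' @param head_out Output features of the per-scale head (default 3).
#' @param n_timepoints Fingerprint length (default 35).
#' @param variant Model variant, see Details.
#' @return Object of class `mrf_regressor_spec`.
#' @export
regressor_spec <- function(backbone_kernels = c(17L, 11L, 7L),
                           backbone_channels = c(128L, 256L, 512L),
                           dropout_p = 0.2, n_heads = 8L,
                           head_hidden = 128L, head_out = 3L,
                           n_timepoints = 35L,
                           variant = c("WPDaCNN", "PDCNN", "DCNN", "SCNN")) {
  variant <- match.arg(variant)
  backbone_kernels <- as.integer(backbone_kernels)
  backbone_channels <- as.integer(backbone_channels)
  if (length(backbone_kernels) != length(backbone_channels)) {
    abort("kernels and channels must have equal length.")
  }
  if (any(backbone_kernels < 1L)) abort("kernels must be positive.")
  if (any(backbone_channels %% as.integer(n_heads) != 0L)) {
    abort("every channel count must be divisible by `n_heads`.")
  }
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  lens <- scale_lengths(as.integer(n_timepoints), backbone_kernels)
  if (any(lens < 1L)) abort("backbone kernels exceed the signal length.")
  structure(
    list(backbone_kernels = backbone_kernels,
         backbone_channels = backbone_channels,
         dropout_p = dropout_p, n_heads = as.integer(n_heads),
         head_hidden = as.integer(head_hidden), head_out = as.integer(head_out),
         n_timepoints = as.integer(n_timepoints), variant = variant,
         scale_lengths = lens),
    class = "mrf_regressor_spec"
  )
}

# valid convolutions, stride 1: l' = l - k + 1 per block
scale_lengths <- function(n, kernels) {
  out <- integer(length(kernels)); l <- n
  for (i in seq_along(kernels)) {
    l <- l - kernels[i] + 1L
    out[i] <- l
  }
  out
}

spec_scales <- function(spec) {
  if (spec$variant %in% c("WPDaCNN", "PDCNN")) {
    seq_along(spec$backbone_kernels)
  } else {
    length(spec$backbone_kernels) # DCNN / SCNN: deepest scale only
  }
}

spec_paths <- function(spec) if (spec$variant == "SCNN") 1L else 2L

#' Build an untrained stage-II regressor
#'
#' @param spec An `mrf_regressor_spec`.
#' @param seed Integer seed for weight initialization.
#' @param output_bias Initial bias of the final output layer(s), in ms.
#'   Regression targets are raw milliseconds, so starting the output at a
#'   plausible tissue value shortens the early search; `train_regressor()`
#'   resets it to the training-set means.
#' @return Object of class `mrf_regressor`.
#' @export
build_regressor <- function(spec = regressor_spec(), seed = 1L,
                            output_bias = c(1000, 100)) {
  stopifnot(inherits(spec, "mrf_regressor_spec"))
  nscale <- length(spec$backbone_kernels)
  scales <- spec_scales(spec)
  npath <- spec_paths(spec)
  with_attn <- spec$variant == "WPDaCNN"

  with_seed(seed, {
    params <- list()
    cin <- 1L
    params$backbone <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      params$backbone[[s]] <- list(
        w = init_conv(spec$backbone_channels[s], cin, spec$backbone_kernels[s]),
        b = numeric(spec$backbone_channels[s])
      )
      cin <- spec$backbone_channels[s]
    }
    params$path <- vector("list", npath)
    for (p in seq_len(npath)) {
      pp <- list(scale = stats::setNames(vector("list", length(scales)),
                                         paste0("s", scales)))
      for (si in seq_along(scales)) {
        s <- scales[si]
        ch <- spec$backbone_channels[s]
        flat_n <- ch * spec$scale_lengths[s]
        blk <- list(
          fc1 = list(w = init_fc(spec$head_hidden, flat_n), b = numeric(spec$head_hidden)),
          fc2 = list(w = init_fc(spec$head_out, spec$head_hidden), b = numeric(spec$head_out))
        )
        if (with_attn) {
          blk$attn <- new_attention_weights(ch, spec$n_heads)
          blk$gamma_attn <- 0 # closed residual branch at init
        }
        pp$scale[[si]] <- blk
      }
      if (with_attn) {
        pp$gamma_scale <- rep(1 / length(scales), length(scales))
      }
      n_out <- if (spec$variant == "SCNN") 2L else 1L
      pp$out <- list(w = init_fc(n_out, spec$head_out, gain = 1),
                     b = if (spec$variant == "SCNN") output_bias[1:2]
                         else output_bias[p])
      params$path[[p]] <- pp
    }
  })
  structure(
    list(spec = spec, params = params, trained = FALSE),
    class = "mrf_regressor"
  )
}

#' @export
print.mrf_regressor <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<mrf_regressor> %s: kernels %s, channels %s, scales %s, %d path(s)%s\n",
    s$variant, paste(s$backbone_kernels, collapse = "/"),
    paste(s$backbone_channels, collapse = "/"),
    paste(s$scale_lengths[spec_scales(s)], collapse = "/"),
    spec_paths(s), if (isTRUE(x$trained)) " (trained)" else " (untrained)"
  ))
  invisible(x)
}

# forward pass; x: [B, T] -> predictions [B, 2] (t1_ms, t2s_ms)
regressor_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  B <- nrow(x)
  scales <- spec_scales(spec)
  npath <- spec_paths(spec)
  with_attn <- spec$variant == "WPDaCNN"

  x <- apply_input_transform(x, model$input_transform)
  a <- array(t(x), c(1L, ncol(x), B))
  acts <- vector("list", length(spec$backbone_kernels))
  bcache <- vector("list", length(spec$backbone_kernels))
  for (s in seq_along(spec$backbone_kernels)) {
    cv <- conv1d_forward(a, model$params$backbone[[s]]$w,
                         model$params$backbone[[s]]$b, pad = 0L)
    rl <- relu_forward(cv$out)
    dr <- dropout_forward(rl$out, spec$dropout_p, training)
    bcache[[s]] <- list(conv = cv$cache, relu = rl$cache, drop = dr$cache)
    a <- dr$out
    acts[[s]] <- a
  }

  pcache <- vector("list", npath)
  preds <- matrix(0, 2L, B)
  for (p in seq_len(npath)) {
    pp <- model$params$path[[p]]
    scache <- vector("list", length(scales))
    zsum <- matrix(0, spec$head_out, B)
    for (si in seq_along(scales)) {
      s <- scales[si]
      blk <- pp$scale[[si]]
      ai <- acts[[s]]
      if (with_attn) {
        att <- attention_forward(ai, blk$attn, spec$n_heads)
        y <- blk$gamma_attn * att$out + ai
      } else {
        att <- NULL
        y <- ai
      }
      d <- dim(y)
      f <- matrix(y, d[1] * d[2], B)
      f1 <- fc_forward(f, blk$fc1$w, blk$fc1$b)
      r1 <- relu_forward(f1$out)
      f2 <- fc_forward(r1$out, blk$fc2$w, blk$fc2$b)
      scache[[si]] <- list(att = att, attn_out = if (with_attn) att$out,
                           ydims = d, f = f, h1 = f1$cache, r1 = r1$cache,
                           h2in = f2$cache)
      w_s <- if (with_attn) pp$gamma_scale[si] else 1
      zsum <- zsum + w_s * f2$out
      scache[[si]]$h2 <- f2$out
    }
    fo <- fc_forward(zsum, pp$out$w, pp$out$b)
    pcache[[p]] <- list(scale = scache, z = zsum, zin = fo$cache)
    if (spec$variant == "SCNN") {
      preds <- fo$out
    } else {
      preds[p, ] <- fo$out
    }
  }
  list(out = t(preds),
       caches = list(backbone = bcache, paths = pcache, acts = acts))
}

# backward from dout [B, 2]; returns grads matching model$params
regressor_backward <- function(model, caches, dout) {
  spec <- model$spec
  B <- nrow(dout)
  scales <- spec_scales(spec)
  npath <- spec_paths(spec)
  with_attn <- spec$variant == "WPDaCNN"
  nscale <- length(spec$backbone_kernels)

  dacts <- lapply(caches$acts, function(a) array(0, dim(a)))
  grads <- list(backbone = vector("list", nscale), path = vector("list", npath))

  for (p in seq_len(npath)) {
    pp <- model$params$path[[p]]
    pc <- caches$paths[[p]]
    dfo <- if (spec$variant == "SCNN") t(dout) else matrix(dout[, p], 1L, B)
    ob <- fc_backward(dfo, pc$zin, pp$out$w)
    gpath <- list(scale = stats::setNames(vector("list", length(scales)),
                                          names(pp$scale)),
                  out = list(w = ob$dw, b = ob$db))
    dz <- ob$dx
    if (with_attn) gpath$gamma_scale <- numeric(length(scales))

    for (si in seq_along(scales)) {
      s <- scales[si]
      blk <- pp$scale[[si]]
      sc <- pc$scale[[si]]
      w_s <- if (with_attn) pp$gamma_scale[si] else 1
      dh2 <- w_s * dz
      if (with_attn) gpath$gamma_scale[si] <- sum(dz * sc$h2)

      b2 <- fc_backward(dh2, sc$h2in, blk$fc2$w)
      dr1 <- relu_backward(b2$dx, sc$r1)
      b1 <- fc_backward(dr1, sc$h1, blk$fc1$w)
      dy <- array(b1$dx, sc$ydims)

      gblk <- list(fc1 = list(w = b1$dw, b = b1$db),
                   fc2 = list(w = b2$dw, b = b2$db))
      if (with_attn) {
        gblk$gamma_attn <- sum(dy * sc$attn_out)
        ab <- attention_backward(blk$gamma_attn * dy, blk$attn,
                                 sc$att$cache, spec$n_heads)
        gblk$attn <- list(wq = ab$dwq, wk = ab$dwk, wv = ab$dwv, wo = ab$dwo)
        dacts[[s]] <- dacts[[s]] + dy + ab$dx
      } else {
        dacts[[s]] <- dacts[[s]] + dy
      }
      gpath$scale[[si]] <- gblk
    }
    grads$path[[p]] <- gpath
  }

  # backbone: deepest block first, feeding into the previous activation
  dy <- NULL
  for (s in rev(seq_len(nscale))) {
    dy <- if (is.null(dy)) dacts[[s]] else dy + dacts[[s]]
    bc <- caches$backbone[[s]]
    dy <- dropout_backward(dy, bc$drop)
    dy <- relu_backward(dy, bc$relu)
    cb <- conv1d_backward(dy, bc$conv)
    grads$backbone[[s]] <- list(w = cb$dw, b = cb$db)
    dy <- cb$dx
  }
  grads
}

#' Stage-II training loss
#'
#' Combined L1 and mean-absolute-percentage-error loss over all values in
#' the batch: `mean(|y - yp|) + 100 * mean(|y - yp| / y)`. The L1 term keeps
#' the regression in milliseconds; the MAPE term balances T1 (hundreds to
#' thousands of ms) against T2* (tens of ms) so neither dominates.
#'
#' @param y True parameter values (ms), vector or matrix; must be positive.
#' @param yp Predicted values, same shape.
#' @return Single number.
#' @export
stage2_loss <- function(y, yp) {
  y <- as.numeric(y); yp <- as.numeric(yp)
  if (length(y) != length(yp)) abort("shapes differ.")
  if (any(y <= 0)) abort("true relaxation times must be positive.")
  mean(abs(y - yp)) + 100 * mean(abs(y - yp) / y)
}

#' Stage-II training configuration
#'
#' Reference settings: batch 500, Adam at learning rate 0.01 with a 5%
#' per-epoch reduction; 100 epochs for standalone training, 25 when the
#' pretrained stage-I model is attached (the second stage converges fast
#' and overtrains beyond that).
#'
#' @inheritParams stage1_config
#' @param valid_max Cap on validation entries evaluated per epoch for the
#'   checkpoint choice (`Inf` = all; a cap keeps desk-scale runs fast, and
#'   the final reported metrics always use the full validation set).
#' @param whiten Prepend a fixed ZCA-whitening input layer computed from the
#'   training split (default `TRUE`). The fingerprint directions that encode
#'   T1 carry orders of magnitude less variance than those encoding T2*
#'   under long-TR schedules; whitening equalizes them so the regression
#'   sees a well-conditioned input.
#' @param whiten_gain_cap Upper bound on the amplification any input
#'   direction can receive from whitening (guards against blowing up noise
#'   in near-null directions at inference).
#' @param selection Checkpoint selection rule: `"valid"` (default; lowest
#'   validation loss, falling back to training loss when the validation set
#'   is empty), `"train"` (lowest training loss), or `"final"` (last epoch).
#'   `"final"` is the appropriate rule for extrapolation probes, where
#'   early-stopping on the out-of-range validation loss would stop on the
#'   very failure being measured.
#' @return Object of class `mrf_stage2_config`.
#' @export
stage2_config <- function(batch_size = 500L, learning_rate = 0.01,
                          lr_decay_per_epoch = 0.05, epochs = 100L,
                          valid_max = Inf, whiten = TRUE,
                          whiten_gain_cap = 1000,
                          selection = c("valid", "train", "final"),
                          seed = 1L) {
  selection <- match.arg(selection)
  assert_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch >= 1) {
    abort("`lr_decay_per_epoch` must be in (0, 1).")
  }
  assert_scalar_num(whiten_gain_cap, "whiten_gain_cap", positive = TRUE)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         lr_decay_per_epoch = lr_decay_per_epoch, epochs = as.integer(epochs),
         valid_max = valid_max, whiten = isTRUE(whiten),
         whiten_gain_cap = whiten_gain_cap, selection = selection,
         seed = as.integer(seed)),
    class = "mrf_stage2_config"
  )
}

# ZCA whitening from training fingerprints, with capped per-direction gain
compute_whitening <- function(x, gain_cap) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / max(1, nrow(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  lmax <- max(lam)
  if (lmax <= 0) abort("whitening: training signals have zero variance.")
  scl <- 1 / sqrt(lam + lmax / gain_cap^2)
  list(center = mu, W = e$vectors %*% (scl * t(e$vectors)))
}

apply_input_transform <- function(x, tf) {
  if (is.null(tf)) return(x)
  sweep(x, 2, tf$center) %*% tf$W
}

#' Train the stage-II regressor
#'
#' Trains on the clean dictionary fingerprints of the split's training
#' entries, with (T1, T2*) in raw milliseconds as targets, and selects the
#' epoch checkpoint with the lowest validation loss (training loss when the
#' validation set is empty). L1 and MAPE components are recorded separately
#' per epoch for both sets.
#'
#' @param dict An `mrf_dictionary`.
#' @param split An `mrf_split` over `dict`.
#' @param spec An `mrf_regressor_spec`.
#' @param cfg An `mrf_stage2_config`.
#' @return A trained `mrf_regressor` with `history` (tibble: epoch, set, loss,
#'   l1_ms, mape_pct, lr) and `best_epoch` attached.
#' @export
train_regressor <- function(dict, split, spec = regressor_spec(),
                            cfg = stage2_config()) {
  stopifnot(inherits(dict, "mrf_dictionary"), inherits(split, "mrf_split"),
            inherits(spec, "mrf_regressor_spec"), inherits(cfg, "mrf_stage2_config"))
  tr_x <- dict$signals[split$train_indices, , drop = FALSE]
  tr_y <- as.matrix(dict$params[split$train_indices, c("t1_ms", "t2s_ms")])
  if (nrow(tr_x) == 0L) abort("empty training split.")
  va_x <- dict$signals[split$valid_indices, , drop = FALSE]
  va_y <- as.matrix(dict$params[split$valid_indices, c("t1_ms", "t2s_ms")])
  has_valid <- nrow(va_x) > 0L

  model <- build_regressor(spec, seed = derive_seed(cfg$seed, 11L),
                           output_bias = colMeans(tr_y))
  if (cfg$whiten) {
    model$input_transform <- compute_whitening(tr_x, cfg$whiten_gain_cap)
  }
  flat <- flatten_params(model$params)
  opt <- adam_init(flat)
  n <- nrow(tr_x)
  lr <- cfg$learning_rate
  best <- list(loss = Inf, params = NULL, epoch = NA_integer_)
  hist <- list()

  eval_metrics <- function(x, y, max_n = Inf, subsample_seed = NULL) {
    if (is.finite(max_n) && nrow(x) > max_n) {
      idx <- with_seed(subsample_seed,
                       sample.int(nrow(x), as.integer(max_n)))
      x <- x[idx, , drop = FALSE]; y <- y[idx, , drop = FALSE]
    }
    yp <- predict_params(model, x, chunk = 2048L)
    list(loss = stage2_loss(y, yp),
         l1 = mean(abs(y - yp)),
         mape = 100 * mean(abs(y - yp) / y))
  }

  with_seed(derive_seed(cfg$seed, 12L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_l1 <- 0; ep_mape <- 0; ep_n <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- tr_x[idx, , drop = FALSE]
        yb <- tr_y[idx, , drop = FALSE]
        fw <- regressor_forward(model, xb, training = TRUE)
        yp <- fw$out
        loss <- stage2_loss(yb, yp)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss).", epoch))
        }
        nvals <- length(yb)
        dyp <- (-sign(yb - yp) * (1 + 100 / yb)) / nvals
        grads <- flatten_params(regressor_backward(model, fw$caches, dyp))
        st <- adam_step(flat, grads, opt, lr)
        flat <- st$params; opt <- st$state
        model$params <- unflatten_params(flat, model$params)

        ep_loss <- ep_loss + loss * length(idx)
        ep_l1 <- ep_l1 + mean(abs(yb - yp)) * length(idx)
        ep_mape <- ep_mape + 100 * mean(abs(yb - yp) / yb) * length(idx)
        ep_n <- ep_n + length(idx)
      }
      tr_row <- tibble::tibble(
        epoch = epoch, set = "train", loss = ep_loss / ep_n,
        l1_ms = ep_l1 / ep_n, mape_pct = ep_mape / ep_n, lr = lr
      )
      hist[[length(hist) + 1L]] <- tr_row
      if (has_valid) {
        vm <- eval_metrics(va_x, va_y, cfg$valid_max,
                           subsample_seed = derive_seed(cfg$seed, 13L))
        hist[[length(hist) + 1L]] <- tibble::tibble(
          epoch = epoch, set = "valid", loss = vm$loss,
          l1_ms = vm$l1, mape_pct = vm$mape, lr = lr
        )
      }
      sel_loss <- switch(cfg$selection %||% "valid",
        valid = if (has_valid) vm$loss else tr_row$loss,
        train = tr_row$loss,
        final = -epoch # monotone decreasing: the last epoch always wins
      )
      if (sel_loss < best$loss) {
        best <- list(loss = sel_loss, params = model$params, epoch = epoch)
      }
      lr <- lr * (1 - cfg$lr_decay_per_epoch)
    }
  })

  model$params <- best$params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$config <- cfg
  model$selection <- cfg$selection %||% "valid"
  # trained range, used to clamp inference like the (bounded) dictionary does
  model$target_range <- cbind(apply(tr_y, 2, min), apply(tr_y, 2, max))
  model
}

#' Predict T1/T2* from fingerprints with a trained regressor
#'
#' Inference runs with dropout disabled, so repeated calls are bit-identical.
#'
#' @param model An `mrf_regressor`.
#' @param signals Numeric vector (one fingerprint) or `B x T` matrix;
#'   fingerprints should be on the unit-norm scale the model was trained on.
#' @param chunk Batch size used internally.
#' @param clamp Clamp predictions to the trained target range (default
#'   `TRUE` for trained models). Dictionary matching can never return a
#'   value outside its grid; clamping gives the regressor the same bounded
#'   codomain, which stabilizes out-of-distribution (e.g. very noisy)
#'   inputs.
#' @return `B x 2` matrix with columns `t1_ms`, `t2s_ms` (a length-2 vector
#'   for a single fingerprint).
#' @export
predict_params <- function(model, signals, chunk = 2048L, clamp = TRUE) {
  stopifnot(inherits(model, "mrf_regressor"))
  vec <- is.null(dim(signals))
  x <- if (vec) matrix(signals, 1L) else as.matrix(signals)
  out <- matrix(NA_real_, nrow(x), 2L,
                dimnames = list(NULL, c("t1_ms", "t2s_ms")))
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    out[idx, ] <- regressor_forward(model, x[idx, , drop = FALSE],
                                    training = FALSE)$out
  }
  if (clamp && !is.null(model$target_range)) {
    for (j in 1:2) {
      out[, j] <- pmin(pmax(out[, j], model$target_range[j, 1]),
                       model$target_range[j, 2])
    }
  }
  if (vec) drop(out) else out
}

#' Parametric maps container
#' @param t1_map,t2s_map `X x Y` matrices in ms.
#' @param brain_mask `X x Y` binary matrix.
#' @return Object of class `mrf_maps`.
#' @export
parametric_maps <- function(t1_map, t2s_map, brain_mask = NULL) {
  if (!all(dim(t1_map) == dim(t2s_map))) abort("map dimensions differ.")
  if (is.null(brain_mask)) brain_mask <- (t1_map > 0) + 0L
  structure(list(t1_map = t1_map, t2s_map = t2s_map, brain_mask = brain_mask),
            class = "mrf_maps")
}

#' @export
print.mrf_maps <- function(x, ...) {
  cat(sprintf("<mrf_maps> %d x %d, %d masked-in voxels\n",
              nrow(x$t1_map), ncol(x$t1_map), sum(x$brain_mask)))
  invisible(x)
}

#' Two-stage prediction of parametric maps
#'
#' Voxel-wise: the fingerprint is L2-normalized, passed through the frozen
#' stage-I denoiser (skipped when `denoiser` is `NULL`, giving the
#' single-stage variant), then through the stage-II regressor. Voxels
#' outside the brain mask, and zero-signal voxels, are written as 0.
#'
#' @param denoiser A trained `mrf_denoiser`, or `NULL` for single-stage.
#' @param regressor A trained `mrf_regressor`.
#' @param stack An `mrf_stack`.
#' @return An `mrf_maps` with `t1_map` and `t2s_map` in ms.
#' @export
predict_two_stage <- function(denoiser, regressor, stack) {
  if (!inherits(stack, "mrf_stack")) stack <- baseline_stack(stack)
  stopifnot(inherits(regressor, "mrf_regressor"))
  if (!is.null(denoiser)) stopifnot(inherits(denoiser, "mrf_denoiser"))
  sv <- stack_voxels(stack)
  q <- l2_normalize_rows(sv$signals)
  zero <- attr(q, "zero_rows")
  attr(q, "zero_rows") <- NULL
  if (!is.null(denoiser)) q <- denoise_signal(denoiser, q)
  yp <- predict_params(regressor, q)
  if (length(zero)) yp[zero, ] <- 0
  fill <- function(v) {
    m <- matrix(0, sv$dims[1], sv$dims[2]); m[sv$keep] <- v; m
  }
  parametric_maps(fill(yp[, 1]), fill(yp[, 2]), stack$brain_mask)
}
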