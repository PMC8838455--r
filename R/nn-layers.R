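# Minimal 1D neural-network primitives with hand-written backward passes.
#
# Activation tensors are 3D arrays [channels, length, batch]; weights are
# plain numeric arrays. Every forward returns the cache its backward needs.
# The heavy lifting is BLAS matrix products, so batches should be large.

# --- initializers ------------------------------------------------------------

# He/Kaiming normal for ReLU stacks: sd = sqrt(2 / fan_in)
init_conv <- function(c_out, c_in, k) {
  array(rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))), c(c_out, c_in, k))
}

init_fc <- function(n_out, n_in, gain = 2) {
  matrix(rnorm(n_out * n_in, sd = sqrt(gain / n_in)), n_out, n_in)
}

# Xavier-style for attention projections (no nonlinearity in between)
init_attn <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in, sd = sqrt(1 / n_in)), n_out, n_in)
}

# --- conv1d ------------------------------------------------------------------

# x: [Cin, L, B]; w: [Cout, Cin, k]; b: length Cout. Stride 1.
# im2col + GEMM in compiled code (src/kernels.cpp).
conv1d_forward <- function(x, w, b, pad = 0L) {
  list(out = cpp_conv1d_fwd(x, w, as.numeric(b), as.integer(pad)),
       cache = list(x = x, w = w, pad = pad))
}

conv1d_backward <- function(dy, cache) {
  out <- cpp_conv1d_bwd(cache$x, cache$w, dy, as.integer(cache$pad))
  out$db <- as.numeric(out$db)
  out
}

# --- batch normalization over channels ---------------------------------------

# Normalizes each channel over (length, batch). eps matches common practice.
bn_forward <- function(x, gamma, beta, running, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, C, d[2] * d[3])
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    nel <- d[2] * d[3]
    unbias <- if (nel > 1) nel / (nel - 1) else 1
    running$var <- (1 - momentum) * running$var + momentum * v * unbias
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  y <- xhat * gamma + beta
  list(out = array(y, d), running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d,
                    training = training))
}

bn_backward <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; n <- d[2] * d[3]
  dym <- matrix(dy, C, n)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    g <- cache$gamma
    dxhat <- dym * g
    dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                         cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- dym * cache$gamma * cache$inv
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# --- simple activations ------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  keep <- array(runif(length(x)) >= p, dim(x)) / (1 - p)
  list(out = x * keep, cache = keep)
}

dropout_backward <- function(dy, keep) {
  if (is.null(keep)) dy else dy * keep
}

# --- fully connected ---------------------------------------------------------

# x: [n_in, B]; w: [n_out, n_in]; b: length n_out
fc_forward <- function(x, w, b) {
  list(out = w %*% x + b, cache = x)
}

fc_backward <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = dy %*% t(x), db = rowSums(dy))
}

# --- Adam optimizer ----------------------------------------------------------

# params/grads are flat named lists of numeric arrays of matching shapes.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0), # preserves each shape exactly
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flatten nested parameter lists to one level for the optimizer;
# unnamed list elements are addressed positionally
flatten_params <- function(x, prefix = "") {
  out <- list()
  keys <- names(x) %||% as.character(seq_along(x))
  keys[!nzchar(keys)] <- as.character(which(!nzchar(keys)))
  for (i in seq_along(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(x[[i]])) {
      out <- c(out, flatten_params(x[[i]], key))
    } else {
      out[[key]] <- x[[i]]
    }
  }
  out
}

unflatten_params <- function(flat, skeleton, prefix = "") {
  keys <- names(skeleton) %||% as.character(seq_along(skeleton))
  keys[!nzchar(keys)] <- as.character(which(!nzchar(keys)))
  for (i in seq_along(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", keys[i]) else keys[i]
    if (is.list(skeleton[[i]])) {
      skeleton[[i]] <- unflatten_params(flat, skeleton[[i]], key)
    } else if (!is.null(flat[[key]])) {
      skeleton[[i]] <- flat[[key]]
    }
  }
  skeleton
}
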