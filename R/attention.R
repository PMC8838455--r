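# Multi-head scaled dot-product self-attention over 1D feature maps.
#
# Orientation: positions are the length axis, features are channels. A
# feature map [d_ch, l] (channels x positions) is, per sample, the transpose
# of the conventional X in R^{l x d_ch}. Channels are sliced contiguously
# into h groups of d_s = d_ch / h; head i projects its slice with its own
# d_s x d_s query/key/value matrices, heads are concatenated and projected
# by W^O in R^{(h d_s) x d_ch}. No projection biases.

new_attention_weights <- function(d_ch, n_heads) {
  if (d_ch %% n_heads != 0L) abort("`d_ch` must be divisible by `n_heads`.")
  ds <- d_ch %/% n_heads
  list(
    wq = array(apply(array(0, c(1, n_heads)), 2, function(.) init_attn(ds, ds)),
               c(ds, ds, n_heads)),
    wk = array(apply(array(0, c(1, n_heads)), 2, function(.) init_attn(ds, ds)),
               c(ds, ds, n_heads)),
    wv = array(apply(array(0, c(1, n_heads)), 2, function(.) init_attn(ds, ds)),
               c(ds, ds, n_heads)),
    wo = init_attn(n_heads * ds, d_ch)
  )
}

# The per-head computations are folded into one "head x batch" axis of size
# HB = n_heads * B; the batched contractions and softmax run in compiled
# code (src/kernels.cpp).

# project all heads: x [d_ch, L, B] -> [ds, L, h, B] (flattened to [ds, L, HB])
project_heads <- function(x, w3, ds, h, L, B) {
  out <- array(0, c(ds, L, h, B))
  for (i in seq_len(h)) {
    sl <- ((i - 1L) * ds + 1L):(i * ds)
    ai <- matrix(x[sl, , , drop = FALSE], ds, L * B)
    out[, , i, ] <- array(crossprod(w3[, , i], ai), c(ds, L, B))
  }
  dim(out) <- c(ds, L, h * B)
  out
}

# x: [d_ch, L, B]; returns out [d_ch, L, B] plus cache
attention_forward <- function(x, w, n_heads) {
  d <- dim(x); d_ch <- d[1]; L <- d[2]; B <- d[3]
  h <- n_heads; ds <- d_ch %/% h; HB <- h * B
  sc <- 1 / sqrt(ds)

  qt <- project_heads(x, w$wq, ds, h, L, B)
  kt <- project_heads(x, w$wk, ds, h, L, B)
  vt <- project_heads(x, w$wv, ds, h, L, B)

  # scores s[p, q, hb] = sc * sum_d qt[d, p, hb] kt[d, q, hb], softmax over q
  s <- cpp_bmm_nt(qt, kt) * sc
  pm <- cpp_softmax_dim2(s)

  # head output hh[d, p, hb] = sum_q vt[d, q, hb] pm[p, q, hb]
  hh <- cpp_bmm_pv(vt, pm)

  # reorder (ds, L, h, B) -> features (ds, h) by position by sample
  dim(hh) <- c(ds, L, h, B)
  ht <- aperm(hh, c(1, 3, 2, 4))
  dim(ht) <- c(d_ch, L, B)
  out <- array(crossprod(w$wo, matrix(ht, d_ch, L * B)), c(d_ch, L, B))
  list(out = out,
       cache = list(x = x, qt = qt, kt = kt, vt = vt, pm = pm, ht = ht,
                    dims = d, ds = ds, sc = sc))
}

attention_backward <- function(dout, w, cache, n_heads) {
  d <- cache$dims; d_ch <- d[1]; L <- d[2]; B <- d[3]
  h <- n_heads; ds <- cache$ds; HB <- h * B
  sc <- cache$sc
  qt <- cache$qt; kt <- cache$kt; vt <- cache$vt; pm <- cache$pm

  dom <- matrix(dout, d_ch, L * B)
  dwo <- matrix(cache$ht, d_ch, L * B) %*% t(dom)
  dht <- array(w$wo %*% dom, c(ds, h, L, B))
  dhh <- aperm(dht, c(1, 3, 2, 4)) # -> (ds, L, h, B)
  dim(dhh) <- c(ds, L, HB)

  # dP[p, q, hb] = sum_d dhh[d, p, hb] vt[d, q, hb]
  dp <- cpp_bmm_nt(dhh, vt)

  # dV[d, q, hb] = sum_p dhh[d, p, hb] pm[p, q, hb]
  dvt <- cpp_bmm_ptv(dhh, pm)

  # softmax backward over the key axis
  dsc <- cpp_softmax_bwd_dim2(dp, pm)

  # dQ[d, p, hb] = sc * sum_q kt[d, q, hb] dsc[p, q, hb]
  dqt4 <- cpp_bmm_pv(kt, dsc) * sc
  # dK[d, q, hb] = sc * sum_p qt[d, p, hb] dsc[p, q, hb]
  dkt4 <- cpp_bmm_ptv(qt, dsc) * sc
  dvt4 <- dvt
  dim(dqt4) <- c(ds, L, h, B)
  dim(dkt4) <- c(ds, L, h, B)
  dim(dvt4) <- c(ds, L, h, B)
  dx <- array(0, d)
  dwq <- array(0, dim(w$wq)); dwk <- array(0, dim(w$wk)); dwv <- array(0, dim(w$wv))
  for (i in seq_len(h)) {
    sl <- ((i - 1L) * ds + 1L):(i * ds)
    ai <- matrix(cache$x[sl, , , drop = FALSE], ds, L * B)
    dqm <- matrix(dqt4[, , i, ], ds, L * B)
    dkm <- matrix(dkt4[, , i, ], ds, L * B)
    dvm <- matrix(dvt4[, , i, ], ds, L * B)
    dwq[, , i] <- ai %*% t(dqm)
    dwk[, , i] <- ai %*% t(dkm)
    dwv[, , i] <- ai %*% t(dvm)
    dai <- w$wq[, , i] %*% dqm + w$wk[, , i] %*% dkm + w$wv[, , i] %*% dvm
    dx[sl, , ] <- array(dai, c(ds, L, B))
  }
  list(dx = dx, dwq = dwq, dwk = dwk, dwv = dwv, dwo = dwo)
}

#' Multi-head scaled dot-product self-attention
#'
#' Applies multi-head self-attention to a single feature map `X` of shape
#' `l x d_ch` (positions by channels). Channels are split contiguously into
#' `n_heads` groups of `d_s = d_ch / n_heads`; head `i` computes
#' `softmax(Q_i K_i' / sqrt(d_s)) V_i` from its own `d_s x d_s` projections
#' of the i-th channel slice, and the concatenated heads are projected by
#' `W^O`.
#'
#' @param X `l x d_ch` numeric matrix.
#' @param weights List with `wq`, `wk`, `wv` (`d_s x d_s x n_heads` arrays)
#'   and `wo` (`(n_heads * d_s) x d_ch`); `NULL` draws random weights.
#' @param n_heads Number of heads (default 8); must divide `d_ch`.
#' @param seed Seed for random weights when `weights` is `NULL`.
#' @return `l x d_ch` matrix.
#' @export
multihead_attention <- function(X, weights = NULL, n_heads = 8L, seed = 1L) {
  X <- as.matrix(X)
  d_ch <- ncol(X)
  if (d_ch %% n_heads != 0L) abort("`ncol(X)` must be divisible by `n_heads`.")
  if (is.null(weights)) {
    weights <- with_seed(seed, new_attention_weights(d_ch, n_heads))
  }
  xarr <- array(t(X), c(d_ch, nrow(X), 1L))
  out <- attention_forward(xarr, weights, n_heads)$out
  t(matrix(out, d_ch, nrow(X)))
}

#' Gamma-weighted residual connection
#'
#' `Y = gamma * Xa + X`: the attention output `Xa` enters through a learnable
#' scalar gate added back onto its input `X`. With `gamma = 0` the attention
#' branch is closed and the block is the identity.
#'
#' @param X,Xa Equal-shape numeric arrays.
#' @param gamma Single numeric scalar.
#' @return Array of the same shape.
#' @export
gamma_residual <- function(X, Xa, gamma) {
  if (!identical(dim(X) %||% length(X), dim(Xa) %||% length(Xa))) {
    abort("`X` and `Xa` must have identical shapes.")
  }
  assert_scalar_num(gamma, "gamma")
  gamma * Xa + X
}
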