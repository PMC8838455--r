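#' Match one fingerprint against a dictionary
#'
#' The query is L2-normalized and compared with every (already unit-norm)
#' dictionary fingerprint by inner product; the entry with the largest dot
#' product -- equivalently the largest cosine similarity -- wins, ties broken
#' by the lowest row index. A zero-norm query cannot be matched and is
#' returned with `index = NA` and `score = NA`.
#'
#' @param query Numeric vector, one fingerprint (length = dictionary signal
#'   length).
#' @param dict An `mrf_dictionary`.
#' @return List with `t1_ms`, `t2s_ms`, `b1`, `score` (best inner product)
#'   and `index` (dictionary row).
#' @export
match_signal <- function(query, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  query <- as.numeric(query)
  if (length(query) != ncol(dict$signals)) {
    abort("query length does not match the dictionary signal length.")
  }
  assert_finite(query, "query")
  nrm <- sqrt(sum(query^2))
  if (nrm <= 0) {
    return(list(t1_ms = NA_real_, t2s_ms = NA_real_, b1 = NA_real_,
                score = NA_real_, index = NA_integer_))
  }
  scores <- as.numeric(dict$signals %*% (query / nrm))
  j <- which.max(scores) # first max = lowest index on ties
  list(t1_ms = dict$params$t1_ms[j], t2s_ms = dict$params$t2s_ms[j],
       b1 = dict$params$b1[j], score = scores[j], index = j)
}

#' Construct a baseline image stack
#'
#' @param data `X x Y x n_timepoints` numeric array (one slice of baseline
#'   images), arbitrary units.
#' @param brain_mask `X x Y` binary matrix; defaults to all-inside.
#' @return Object of class `mrf_stack`.
#' @export
baseline_stack <- function(data, brain_mask = NULL) {
  if (length(dim(data)) == 4L && dim(data)[3] == 1L) {
    data <- array(data, dim(data)[c(1, 2, 4)]) # accept (X, Y, 1, T) NIfTI layout
  }
  if (length(dim(data)) != 3L) abort("`data` must be an X x Y x T array.")
  if (is.null(brain_mask)) {
    brain_mask <- matrix(1L, dim(data)[1], dim(data)[2])
  }
  brain_mask <- matrix(as.integer(brain_mask != 0), dim(data)[1], dim(data)[2])
  if (!all(dim(brain_mask) == dim(data)[1:2])) {
    abort("`brain_mask` dimensions must match the stack's spatial dimensions.")
  }
  structure(list(data = data, brain_mask = brain_mask), class = "mrf_stack")
}

#' @export
print.mrf_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mrf_stack> %d x %d x %d time points, %d masked-in voxels\n",
              d[1], d[2], d[3], sum(x$brain_mask)))
  invisible(x)
}

# flatten masked voxels to a voxel x time matrix
stack_voxels <- function(stack) {
  d <- dim(stack$data)
  mat <- matrix(stack$data, d[1] * d[2], d[3])
  keep <- which(stack$brain_mask != 0)
  list(signals = mat[keep, , drop = FALSE], keep = keep, dims = d[1:2])
}

#' Match every voxel of a baseline stack
#'
#' Voxel-wise inner-product matching inside the brain mask. Voxels outside
#' the mask, and zero-signal voxels inside it, are written as 0 in the output
#' maps; the number of unmatched in-mask voxels is reported.
#'
#' @param stack An `mrf_stack` (or bare `X x Y x T` array).
#' @param dict An `mrf_dictionary`.
#' @param block_size Voxels matched per matrix-product block (memory knob).
#' @return Object of class `mrf_match`: list of `X x Y` maps `t1_map`,
#'   `t2s_map` (ms), `b1_map`, `score_map`, `index_map`, plus
#'   `n_unmatched` and the mask.
#' @export
match_stack <- function(stack, dict, block_size = 4096L) {
  if (!inherits(stack, "mrf_stack")) stack <- baseline_stack(stack)
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (dim(stack$data)[3] != ncol(dict$signals)) {
    abort("stack and dictionary disagree on the number of time points.")
  }
  sv <- stack_voxels(stack)
  q <- l2_normalize_rows(sv$signals)
  zero <- attr(q, "zero_rows")

  nvox <- nrow(q)
  best_idx <- integer(nvox); best_score <- numeric(nvox)
  sigs <- dict$signals
  for (start in seq(1L, max(nvox, 1L), by = block_size)) {
    if (nvox == 0L) break
    idx <- start:min(start + block_size - 1L, nvox)
    sc <- sigs %*% t(q[idx, , drop = FALSE]) # N x block
    best_idx[idx] <- max.col(t(sc), ties.method = "first")
    best_score[idx] <- sc[cbind(best_idx[idx], seq_along(idx))]
  }
  if (length(zero)) {
    best_idx[zero] <- NA_integer_
    best_score[zero] <- NA_real_
  }

  fill <- function(vals) {
    m <- matrix(0, sv$dims[1], sv$dims[2])
    m[sv$keep] <- ifelse(is.na(vals), 0, vals)
    m
  }
  structure(
    list(
      t1_map = fill(dict$params$t1_ms[best_idx]),
      t2s_map = fill(dict$params$t2s_ms[best_idx]),
      b1_map = fill(dict$params$b1[best_idx]),
      score_map = fill(best_score),
      index_map = fill(best_idx),
      n_unmatched = length(zero),
      brain_mask = stack$brain_mask
    ),
    class = "mrf_match"
  )
}

#' @export
print.mrf_match <- function(x, ...) {
  cat(sprintf("<mrf_match> %d x %d maps, %d unmatched voxels\n",
              nrow(x$t1_map), ncol(x$t1_map), x$n_unmatched))
  invisible(x)
}

#' Signal-to-noise ratio of a matched signal (dB)
#'
#' `SNR = 10 log10( sum(s^2) / sum(n^2) )` where `s` is the matched
#' (noise-free) dictionary signal and `n` the residual between the scanned
#' and matched signal. A zero-energy residual returns `Inf`.
#'
#' @param s Matched signal values.
#' @param n Residual values, same length as `s`.
#' @return SNR in dB.
#' @export
#' @examples
#' compute_snr(rep(1, 35), rep(0.1, 35)) # exactly 20 dB
compute_snr <- function(s, n) {
  s <- as.numeric(s); n <- as.numeric(n)
  if (length(s) != length(n)) abort("`s` and `n` must have equal length.")
  es <- sum(s^2)
  if (!is.finite(es) || es <= 0) abort("`s` must have positive, finite energy.")
  en <- sum(n^2)
  if (en == 0) return(Inf)
  10 * log10(es / en)
}

#' Extract an empirical noise bank from a scanned stack
#'
#' Each in-mask voxel signal is L2-normalized and matched against the
#' dictionary; the residual (normalized scan minus matched unit-norm entry)
#' is stored as one row of the bank, and the voxel SNR is computed from the
#' matched signal and the residual. The flattened pool of residual values is
#' kept alongside, for order-free sampling: the temporal position of a
#' residual value carries no information once the matched signal is removed.
#'
#' @param stack An `mrf_stack`.
#' @param dict An `mrf_dictionary` (the densest available grid).
#' @param source_meta Optional character label (slice/subject provenance).
#' @return List with `bank` (class `mrf_noise_bank`: `residuals` M x T matrix,
#'   `pooled_values`, `source_meta`) and `snr_map` (X x Y dB matrix, `Inf`
#'   where the residual is exactly zero, 0 outside the mask).
#' @export
extract_noise_bank <- function(stack, dict, source_meta = NULL) {
  if (!inherits(stack, "mrf_stack")) stack <- baseline_stack(stack)
  stopifnot(inherits(dict, "mrf_dictionary"))
  mres <- match_stack(stack, dict)
  sv <- stack_voxels(stack)
  q <- l2_normalize_rows(sv$signals)
  zero <- attr(q, "zero_rows")
  idx <- mres$index_map[sv$keep]
  ok <- !(seq_len(nrow(q)) %in% zero)
  matched <- dict$signals[idx[ok], , drop = FALSE]
  res <- q[ok, , drop = FALSE] - matched

  snr <- numeric(nrow(q))
  en <- rowSums(res^2)
  es <- rowSums(matched^2)
  snr[ok] <- ifelse(en == 0, Inf, 10 * log10(es / en))
  snr[!ok] <- NA_real_
  snr_map <- matrix(0, sv$dims[1], sv$dims[2])
  snr_map[sv$keep] <- snr

  bank <- structure(
    list(residuals = res, pooled_values = as.numeric(res),
         source_meta = source_meta %||% "unlabelled"),
    class = "mrf_noise_bank"
  )
  list(bank = bank, snr_map = snr_map, match = mres)
}

#' Build a noise bank from a matrix of residual vectors
#'
#' Useful for synthetic banks (e.g. white Gaussian residuals at a chosen SNR)
#' and for assembling banks from residuals gathered elsewhere.
#'
#' @param residuals `M x n_timepoints` matrix of signed residual values.
#' @param source_meta Character label describing provenance.
#' @return An `mrf_noise_bank`.
#' @export
noise_bank_from_residuals <- function(residuals, source_meta = "unlabelled") {
  residuals <- as.matrix(residuals)
  assert_finite(residuals, "residuals")
  structure(
    list(residuals = residuals, pooled_values = as.numeric(residuals),
         source_meta = as.character(source_meta)),
    class = "mrf_noise_bank"
  )
}

#' @export
print.mrf_noise_bank <- function(x, ...) {
  cat(sprintf("<mrf_noise_bank> %d residual vectors x %d time points (%s)\n",
              nrow(x$residuals), ncol(x$residuals), x$source_meta))
  invisible(x)
}

#' Sample a residual vector from a noise bank
#'
#' `pooled_iid` draws each of the `n_timepoints` values independently, with
#' replacement, from the flattened pool (temporal order fully discarded);
#' `permuted_vector` draws one stored residual row and permutes its order
#' (preserving each vector's value multiset).
#'
#' @param bank An `mrf_noise_bank`.
#' @param n_timepoints Length of the residual vector to return.
#' @param mode `"pooled_iid"` (default) or `"permuted_vector"`.
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of length `n_timepoints`.
#' @export
sample_noise <- function(bank, n_timepoints,
                         mode = c("pooled_iid", "permuted_vector"),
                         seed = NULL) {
  mode <- match.arg(mode)
  drop(sample_noise_matrix(bank, n_timepoints, 1L, mode = mode, seed = seed))
}

# batched form used by the training loops
sample_noise_matrix <- function(bank, n_timepoints, n_draws,
                                mode = c("pooled_iid", "permuted_vector"),
                                seed = NULL) {
  stopifnot(inherits(bank, "mrf_noise_bank"))
  mode <- match.arg(mode)
  if (length(bank$pooled_values) == 0L) abort("noise bank is empty.")
  n_timepoints <- as.integer(n_timepoints)
  with_seed(seed, {
    if (mode == "pooled_iid") {
      matrix(sample(bank$pooled_values, n_draws * n_timepoints, replace = TRUE),
             n_draws, n_timepoints)
    } else {
      if (n_timepoints != ncol(bank$residuals)) {
        abort("`permuted_vector` requires n_timepoints == bank residual length.")
      }
      rows <- sample.int(nrow(bank$residuals), n_draws, replace = TRUE)
      t(vapply(rows, function(r) sample(bank$residuals[r, ]),
               numeric(n_timepoints)))
    }
  })
}

#' Save / load a noise bank as an HDF5 container
#' @param bank An `mrf_noise_bank`.
#' @param path `.h5` path.
#' @return `path` invisibly / an `mrf_noise_bank`.
#' @export
write_noise_bank <- function(bank, path) {
  stopifnot(inherits(bank, "mrf_noise_bank"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(bank$residuals, path, "residuals")
  rhdf5::h5write(bank$pooled_values, path, "pooled")
  rhdf5::h5write(as.character(bank$source_meta), path, "meta")
  invisible(path)
}

#' @rdname write_noise_bank
#' @export
read_noise_bank <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  structure(
    list(residuals = rhdf5::h5read(path, "residuals"),
         pooled_values = as.numeric(rhdf5::h5read(path, "pooled")),
         source_meta = as.character(rhdf5::h5read(path, "meta"))),
    class = "mrf_noise_bank"
  )
}
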