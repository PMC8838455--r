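#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd cor cor.test median setNames predict
#' @importFrom utils head tail write.csv read.csv
NULL

# shared argument checks ------------------------------------------------------

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

# L2-normalize the rows of a matrix; zero rows are left untouched and flagged
# through the "zero_rows" attribute so callers can mark unmatched voxels.
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm <= 0 | !is.finite(nrm)
  nrm[zero] <- 1
  out <- x / nrm
  attr(out, "zero_rows") <- which(zero)
  out
}

deg2rad <- function(deg) deg * pi / 180

# Deterministic child seeds so independent stages never share an RNG stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
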