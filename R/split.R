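#' Split a dictionary by T1/T2* value range
#'
#' Training entries are those whose T1 and T2* both fall inside the given
#' closed intervals; every other entry goes to validation. This is the
#' extrapolation split: the validation set lies outside the trained parameter
#' range, probing whether a regressor has learned the underlying signal model
#' rather than interpolated it.
#'
#' @param dict An `mrf_dictionary`.
#' @param t1_train Length-2 numeric, inclusive T1 training range in ms
#'   (default `c(500, 2500)`).
#' @param t2s_train Length-2 numeric, inclusive T2* training range in ms
#'   (default `c(50, 1500)`).
#' @return An object of class `mrf_split`: list with integer vectors
#'   `train_indices`, `valid_indices` and a `method` descriptor.
#' @export
split_by_range <- function(dict, t1_train = c(500, 2500), t2s_train = c(50, 1500)) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  p <- dict$params
  in_train <- p$t1_ms >= t1_train[1] & p$t1_ms <= t1_train[2] &
    p$t2s_ms >= t2s_train[1] & p$t2s_ms <= t2s_train[2]
  if (!any(in_train)) abort("range split produces an empty training set.")
  if (!any(!in_train)) {
    warn("range split covers the whole dictionary; validation set is empty.")
  }
  new_split(which(in_train), which(!in_train),
            list(type = "range", t1_train = t1_train, t2s_train = t2s_train),
            n = nrow(p))
}

#' Split a dictionary by grid-index interval
#'
#' Takes every `interval`-th value of the T1 and the T2* grid, starting from
#' the first, as the training sub-grid; an entry trains iff both its T1 and
#' its T2* grid index lie on the sub-grid (B1+ levels are not subsampled).
#' On a 2% grid, `interval = 2` yields an effective 4% training increment
#' (in general `(1 + f)^interval - 1`); the unsampled entries form the
#' validation set. This is the interpolation split.
#'
#' @param dict An `mrf_dictionary`.
#' @param interval Positive integer stride; `1` returns the whole dictionary
#'   as training with an empty validation set.
#' @return An `mrf_split` (see [split_by_range()]).
#' @export
split_by_increment <- function(dict, interval) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  interval <- as.integer(interval)
  if (is.na(interval) || interval < 1L) abort("`interval` must be >= 1.")
  n_t1 <- length(dict$axes$t1_ms); n_t2s <- length(dict$axes$t2s_ms)
  if (interval > max(n_t1, n_t2s)) {
    abort("`interval` exceeds the grid length; no training entries possible.")
  }
  p <- dict$params
  on_sub <- function(idx) (idx - 1L) %% interval == 0L
  in_train <- on_sub(p$t1_idx) & on_sub(p$t2s_idx)
  if (!any(in_train)) abort("increment split produces an empty training set.")
  new_split(which(in_train), which(!in_train),
            list(type = "increment", interval = interval), n = nrow(p))
}

new_split <- function(train_indices, valid_indices, method, n) {
  structure(
    list(train_indices = as.integer(train_indices),
         valid_indices = as.integer(valid_indices),
         method = method, n = as.integer(n)),
    class = "mrf_split"
  )
}

#' @export
print.mrf_split <- function(x, ...) {
  cat(sprintf("<mrf_split> %s: %d train / %d validation of %d entries\n",
              x$method$type, length(x$train_indices),
              length(x$valid_indices), x$n))
  invisible(x)
}

#' Tidy a dictionary split into a per-entry tibble
#' @param x An `mrf_split`.
#' @param dict Optionally the dictionary it indexes, to attach parameters.
#' @param ... Unused.
#' @return Tibble with `entry` and `set` (`"train"`/`"valid"`), plus the
#'   parameter columns when `dict` is given.
#' @export
tidy.mrf_split <- function(x, dict = NULL, ...) {
  out <- tibble::tibble(
    entry = c(x$train_indices, x$valid_indices),
    set = rep(c("train", "valid"),
              c(length(x$train_indices), length(x$valid_indices)))
  )
  out <- dplyr::arrange(out, .data$entry)
  if (!is.null(dict)) {
    out <- dplyr::bind_cols(out, dict$params[out$entry, , drop = FALSE])
  }
  out
}
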