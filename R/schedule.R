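#' Build an MRF-EPI acquisition schedule
#'
#' An acquisition schedule holds the per-time-point pulse parameters that
#' define the fingerprint: nominal flip angle (degrees), echo time (ms) and
#' repetition time (ms). The default 35-point schedule sweeps flip angle
#' 34--86 degrees, TE 21--81.5 ms and TR 3530--6570 ms linearly, matching the
#' printed ranges of the MRF-EPI protocol; exact per-time-point values are
#' site-specific and can be supplied via `pattern = "custom"` or
#' [read_schedule()].
#'
#' @param n_timepoints Number of baseline images per slice (default 35).
#' @param fa_range_deg Length-2 numeric, flip-angle range in degrees.
#' @param te_range_ms Length-2 numeric, echo-time range in ms.
#' @param tr_range_ms Length-2 numeric, repetition-time range in ms.
#' @param pattern `"linear_up"` (default) interpolates from the first to the
#'   second range element, `"linear_down"` the reverse, `"custom"` takes the
#'   explicit vectors in `fa_deg`, `te_ms`, `tr_ms`.
#' @param fa_deg,te_ms,tr_ms Explicit per-time-point values, used only with
#'   `pattern = "custom"`.
#'
#' @return An object of class `mrf_schedule`: a tibble with columns
#'   `timepoint`, `flip_angle_deg`, `te_ms`, `tr_ms`.
#' @export
#' @examples
#' sch <- make_schedule()
#' sch[c(1, 35), ]
make_schedule <- function(n_timepoints = 35L,
                          fa_range_deg = c(34, 86),
                          te_range_ms = c(21, 81.5),
                          tr_range_ms = c(3530, 6570),
                          pattern = c("linear_up", "linear_down", "custom"),
                          fa_deg = NULL, te_ms = NULL, tr_ms = NULL) {
  pattern <- match.arg(pattern)
  n <- as.integer(n_timepoints)
  if (is.na(n) || n < 1L) abort("`n_timepoints` must be a positive integer.")

  interp <- function(range, rev = FALSE) {
    if (rev) range <- rev(range)
    if (n == 1L) return(range[1])
    seq(range[1], range[2], length.out = n)
  }
  if (pattern == "custom") {
    if (is.null(fa_deg) || is.null(te_ms) || is.null(tr_ms)) {
      abort("`pattern = \"custom\"` requires `fa_deg`, `te_ms` and `tr_ms`.")
    }
    fa <- as.numeric(fa_deg); te <- as.numeric(te_ms); tr <- as.numeric(tr_ms)
    if (length(fa) != n || length(te) != n || length(tr) != n) {
      abort("custom schedule vectors must all have length `n_timepoints`.")
    }
  } else {
    rev <- pattern == "linear_down"
    fa <- interp(fa_range_deg, rev)
    te <- interp(te_range_ms, rev)
    tr <- interp(tr_range_ms, rev)
  }

  validate_schedule_vectors(fa, te, tr)
  out <- tibble::tibble(
    timepoint = seq_len(n),
    flip_angle_deg = fa, te_ms = te, tr_ms = tr
  )
  class(out) <- c("mrf_schedule", class(out))
  out
}

validate_schedule_vectors <- function(fa, te, tr) {
  assert_finite(fa, "flip_angle_deg")
  assert_finite(te, "te_ms")
  assert_finite(tr, "tr_ms")
  if (any(fa <= 0 | fa > 180)) abort("flip angles must lie in (0, 180] degrees.")
  if (any(te <= 0)) abort("echo times must be positive.")
  if (any(tr <= te)) abort("every TR must exceed its TE.")
  invisible(TRUE)
}

#' Read an acquisition schedule from a delimited text file
#'
#' Expects three columns per time point: flip angle (degrees), echo time (ms),
#' repetition time (ms), with or without a header row.
#'
#' @param path Path to a whitespace/comma-delimited text file.
#' @return An `mrf_schedule` (see [make_schedule()]).
#' @export
read_schedule <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) == 1L) {
    raw <- utils::read.table(path, header = FALSE, sep = ",",
                             comment.char = "#", stringsAsFactors = FALSE)
  }
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    # tolerate a header line
    raw <- raw[-1, , drop = FALSE]
    raw[] <- lapply(raw, as.numeric)
  }
  if (ncol(raw) < 3L) abort("schedule files need 3 columns: flip angle, TE, TR.")
  make_schedule(nrow(raw), pattern = "custom",
                fa_deg = raw[[1]], te_ms = raw[[2]], tr_ms = raw[[3]])
}

#' Write a schedule to a 3-column text file
#' @param schedule An `mrf_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  utils::write.table(
    schedule[, c("flip_angle_deg", "te_ms", "tr_ms")],
    path, row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

n_timepoints <- function(schedule) nrow(schedule)
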