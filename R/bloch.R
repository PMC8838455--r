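#' Simulate an MRF-EPI fingerprint from the Bloch equations
#'
#' Single-pass spoiled gradient-echo Bloch solution with ideal spoiling:
#' transverse magnetization is assumed fully dephased before each excitation,
#' so only the longitudinal component is tracked. Starting from thermal
#' equilibrium `Mz(1) = m0`, at time point `i` the effective flip angle is
#' `alpha_i = b1_eff * flip_angle_deg[i]`; the echo amplitude is
#' `s_i = Mz(i) * sin(alpha_i) * exp(-TE_i / T2*)`, and the longitudinal
#' magnetization then relaxes over the remainder of the TR:
#' `Mz(i+1) = m0 + (Mz(i) * cos(alpha_i) - m0) * exp(-TR_i / T1)`.
#' The returned signal is the magnitude, not normalized.
#'
#' @param schedule An `mrf_schedule` from [make_schedule()].
#' @param t1_ms,t2s_ms,b1_eff Tissue parameters: longitudinal relaxation time
#'   (ms), effective transverse relaxation time T2* (ms), and flip-angle
#'   efficiency B1+ (dimensionless). `t1_ms` and `t2s_ms` must be positive;
#'   `b1_eff >= 0` (0 gives the all-zero signal).
#' @param m0 Equilibrium magnetization (arbitrary units, default 1).
#' @param n_prep_cycles Number of un-recorded preparation passes through the
#'   schedule before the recorded pass, for steady-state variants (default 0:
#'   a single pass from equilibrium).
#' @return Numeric vector of length `nrow(schedule)`, arbitrary units.
#' @export
#' @examples
#' sch <- make_schedule(1, c(90, 90), c(50, 50), c(1000, 1000))
#' simulate_fingerprint(sch, t1_ms = 1000, t2s_ms = 50, b1_eff = 1) # sin(90)*exp(-1)
simulate_fingerprint <- function(schedule, t1_ms, t2s_ms, b1_eff = 1,
                                 m0 = 1, n_prep_cycles = 0L) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  assert_scalar_num(t1_ms, "t1_ms", positive = TRUE)
  assert_scalar_num(t2s_ms, "t2s_ms", positive = TRUE)
  assert_scalar_num(b1_eff, "b1_eff")
  if (b1_eff < 0) abort("`b1_eff` must be non-negative.")
  assert_scalar_num(m0, "m0", positive = TRUE)
  drop(simulate_fingerprints(
    schedule, cbind(t1_ms, t2s_ms, b1_eff),
    m0 = m0, n_prep_cycles = n_prep_cycles
  ))
}

#' Simulate many fingerprints at once
#'
#' Vectorized form of [simulate_fingerprint()]: one Bloch recursion pass over
#' the schedule, carried simultaneously for every parameter triple.
#'
#' @inheritParams simulate_fingerprint
#' @param params Numeric matrix or data frame with columns
#'   `t1_ms`, `t2s_ms`, `b1` (in that order if unnamed), one row per entry.
#' @return `nrow(params) x nrow(schedule)` matrix of magnitude signals.
#' @export
simulate_fingerprints <- function(schedule, params, m0 = 1, n_prep_cycles = 0L) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  params <- as.matrix(params)
  if (ncol(params) < 3L) abort("`params` needs columns t1_ms, t2s_ms, b1.")
  t1 <- as.numeric(params[, 1]); t2s <- as.numeric(params[, 2])
  b1 <- as.numeric(params[, 3])
  assert_finite(t1, "t1_ms"); assert_finite(t2s, "t2s_ms"); assert_finite(b1, "b1")
  if (any(t1 <= 0) || any(t2s <= 0)) abort("relaxation times must be positive.")
  if (any(b1 < 0)) abort("B1+ must be non-negative.")

  fa <- deg2rad(schedule$flip_angle_deg)
  te <- schedule$te_ms; tr <- schedule$tr_ms
  n <- length(fa); m <- length(t1)

  sig <- matrix(0, m, n)
  mz <- rep(m0, m)
  passes <- as.integer(n_prep_cycles) + 1L
  for (p in seq_len(passes)) {
    record <- p == passes
    for (i in seq_len(n)) {
      alpha <- b1 * fa[i]
      if (record) sig[, i] <- mz * sin(alpha) * exp(-te[i] / t2s)
      mz <- m0 + (mz * cos(alpha) - m0) * exp(-tr[i] / t1)
    }
  }
  abs(sig)
}
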