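#' Geometric parameter grid
#'
#' Relaxation-time grids are geometric: successive values differ by a fixed
#' fraction, e.g. a 2% grid starting at 100 ms runs 100, 102, 104.04, ...
#' The grid starts exactly at `lo` and includes every value up to and
#' including the largest one not exceeding `hi`.
#'
#' @param lo,hi Grid bounds, `0 < lo < hi`.
#' @param increment_frac Fractional spacing, e.g. `0.02` for 2%.
#' @return Strictly increasing numeric vector `lo * (1 + f)^k`, `k = 0, 1, ...`
#' @export
#' @examples
#' head(make_geometric_grid(100, 4000, 0.02), 3) # 100, 102, 104.04
make_geometric_grid <- function(lo, hi, increment_frac) {
  assert_scalar_num(lo, "lo", positive = TRUE)
  assert_scalar_num(hi, "hi", positive = TRUE)
  assert_scalar_num(increment_frac, "increment_frac", positive = TRUE)
  if (lo >= hi) abort("`lo` must be smaller than `hi`.")
  kmax <- floor(log(hi / lo) / log1p(increment_frac) + 1e-9)
  lo * (1 + increment_frac)^(0:kmax)
}

#' Dictionary grid specification
#'
#' Defines the T1 and T2* geometric grids, the linear B1+ grid, and whether
#' physically implausible entries with T1 < T2* are excluded.
#'
#' @param t1_min_ms,t1_max_ms T1 grid bounds (ms); defaults 100--4000.
#' @param t2s_min_ms,t2s_max_ms T2* grid bounds (ms); defaults 10--3000.
#' @param increment_frac Geometric spacing for both relaxation grids
#'   (default 0.02, i.e. 2%).
#' @param b1_min,b1_max,b1_step Linear B1+ efficiency grid
#'   (defaults 0.6--1.4 in steps of 0.05, 17 levels).
#' @param exclude_t1_lt_t2s Drop entries with T1 < T2* (default `TRUE`).
#' @return An object of class `mrf_grid_spec`.
#' @export
grid_spec <- function(t1_min_ms = 100, t1_max_ms = 4000,
                      t2s_min_ms = 10, t2s_max_ms = 3000,
                      increment_frac = 0.02,
                      b1_min = 0.6, b1_max = 1.4, b1_step = 0.05,
                      exclude_t1_lt_t2s = TRUE) {
  for (nm in c("t1_min_ms", "t1_max_ms", "t2s_min_ms", "t2s_max_ms",
               "b1_min", "b1_max", "b1_step")) {
    assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  if (t1_min_ms >= t1_max_ms) abort("T1 grid: need min < max.")
  if (t2s_min_ms >= t2s_max_ms) abort("T2* grid: need min < max.")
  if (increment_frac <= 0 || increment_frac >= 1) {
    abort("`increment_frac` must be in (0, 1).")
  }
  if (b1_min > b1_max) abort("B1+ grid: need min <= max.")
  structure(
    list(
      t1_min_ms = t1_min_ms, t1_max_ms = t1_max_ms,
      t2s_min_ms = t2s_min_ms, t2s_max_ms = t2s_max_ms,
      increment_frac = increment_frac,
      b1_min = b1_min, b1_max = b1_max, b1_step = b1_step,
      exclude_t1_lt_t2s = isTRUE(exclude_t1_lt_t2s)
    ),
    class = "mrf_grid_spec"
  )
}

grid_axes <- function(spec) {
  stopifnot(inherits(spec, "mrf_grid_spec"))
  b1 <- seq(spec$b1_min, spec$b1_max, by = spec$b1_step)
  # guard the upper endpoint against fp drift of seq()
  b1 <- b1[b1 <= spec$b1_max + 1e-9]
  list(
    t1_ms = make_geometric_grid(spec$t1_min_ms, spec$t1_max_ms, spec$increment_frac),
    t2s_ms = make_geometric_grid(spec$t2s_min_ms, spec$t2s_max_ms, spec$increment_frac),
    b1 = b1
  )
}

#' @export
print.mrf_grid_spec <- function(x, ...) {
  ax <- grid_axes(x)
  cat(sprintf(
    "<mrf_grid_spec> T1 %g-%g ms (%d), T2* %g-%g ms (%d), %g%% spacing, B1+ %g-%g step %g (%d)%s\n",
    x$t1_min_ms, x$t1_max_ms, length(ax$t1_ms),
    x$t2s_min_ms, x$t2s_max_ms, length(ax$t2s_ms),
    100 * x$increment_frac, x$b1_min, x$b1_max, x$b1_step, length(ax$b1),
    if (x$exclude_t1_lt_t2s) ", excluding T1 < T2*" else ""
  ))
  invisible(x)
}
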