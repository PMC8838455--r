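#' Generate an MRF dictionary
#'
#' Crosses the T1 and T2* geometric grids with the linear B1+ grid, drops
#' entries with T1 < T2* when the grid spec requests it, simulates each
#' fingerprint with the Bloch recursion and stores it L2-normalized (the
#' inner-product match is only meaningful up to scale).
#'
#' @param schedule An `mrf_schedule`.
#' @param grid An `mrf_grid_spec` from [grid_spec()].
#' @param m0 Equilibrium magnetization passed to the simulator.
#' @param n_prep_cycles Preparation passes, see [simulate_fingerprint()].
#' @return An object of class `mrf_dictionary`: list with
#'   * `params`: tibble with `t1_ms`, `t2s_ms`, `b1`, `t1_idx`, `t2s_idx`
#'     (1-based positions on the generating grids);
#'   * `signals`: `N x n_timepoints` matrix of unit-norm fingerprints;
#'   * `schedule`, `grid`: the generating inputs;
#'   * `axes`: the grid axis values.
#' @export
generate_dictionary <- function(schedule, grid, m0 = 1, n_prep_cycles = 0L) {
  stopifnot(inherits(schedule, "mrf_schedule"), inherits(grid, "mrf_grid_spec"))
  ax <- grid_axes(grid)
  ent <- expand.grid(
    t1_idx = seq_along(ax$t1_ms),
    t2s_idx = seq_along(ax$t2s_ms),
    b1 = ax$b1,
    KEEP.OUT.ATTRS = FALSE
  )
  ent$t1_ms <- ax$t1_ms[ent$t1_idx]
  ent$t2s_ms <- ax$t2s_ms[ent$t2s_idx]
  if (grid$exclude_t1_lt_t2s) {
    ent <- ent[ent$t1_ms >= ent$t2s_ms, , drop = FALSE]
  }
  if (nrow(ent) == 0L) abort("grid specification produces an empty dictionary.")

  sig <- simulate_fingerprints(
    schedule, cbind(ent$t1_ms, ent$t2s_ms, ent$b1),
    m0 = m0, n_prep_cycles = n_prep_cycles
  )
  sig <- l2_normalize_rows(sig)
  attr(sig, "zero_rows") <- NULL

  params <- tibble::tibble(
    t1_ms = ent$t1_ms, t2s_ms = ent$t2s_ms, b1 = ent$b1,
    t1_idx = as.integer(ent$t1_idx), t2s_idx = as.integer(ent$t2s_idx)
  )
  new_dictionary(params, sig, schedule, grid, ax)
}

new_dictionary <- function(params, signals, schedule, grid, axes) {
  structure(
    list(params = params, signals = signals,
         schedule = schedule, grid = grid, axes = axes),
    class = "mrf_dictionary"
  )
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf(
    "<mrf_dictionary> %d entries x %d time points\n",
    nrow(x$params), ncol(x$signals)
  ))
  cat(sprintf("  T1 %g-%g ms | T2* %g-%g ms | B1+ %g-%g\n",
              min(x$params$t1_ms), max(x$params$t1_ms),
              min(x$params$t2s_ms), max(x$params$t2s_ms),
              min(x$params$b1), max(x$params$b1)))
  invisible(x)
}

#' Subset a dictionary by entry index
#' @param dict An `mrf_dictionary`.
#' @param idx Integer row indices to keep.
#' @return An `mrf_dictionary` with the selected entries.
#' @export
dictionary_subset <- function(dict, idx) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  new_dictionary(dict$params[idx, , drop = FALSE],
                 dict$signals[idx, , drop = FALSE],
                 dict$schedule, dict$grid, dict$axes)
}

# persistence -----------------------------------------------------------------

#' Save / load a dictionary as a single HDF5 container
#'
#' Layout: dataset `params` (N x 3: t1_ms, t2s_ms, b1), dataset `signals`
#' (N x n_timepoints), dataset `grid_idx` (N x 2), groups `schedule` and
#' `grid` holding the generating inputs.
#'
#' @param dict An `mrf_dictionary`.
#' @param path Path of the `.h5` file to create (overwritten if present).
#' @return `path` invisibly (`write_dictionary`); an `mrf_dictionary`
#'   (`read_dictionary`).
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(as.matrix(dict$params[, c("t1_ms", "t2s_ms", "b1")]), path, "params")
  rhdf5::h5write(unclass(dict$signals), path, "signals")
  rhdf5::h5write(as.matrix(dict$params[, c("t1_idx", "t2s_idx")]), path, "grid_idx")
  rhdf5::h5write(as.matrix(dict$schedule[, c("flip_angle_deg", "te_ms", "tr_ms")]),
                 path, "schedule")
  g <- dict$grid
  rhdf5::h5write(c(g$t1_min_ms, g$t1_max_ms, g$t2s_min_ms, g$t2s_max_ms,
                   g$increment_frac, g$b1_min, g$b1_max, g$b1_step,
                   as.numeric(g$exclude_t1_lt_t2s)),
                 path, "grid_spec")
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  p <- rhdf5::h5read(path, "params")
  sig <- rhdf5::h5read(path, "signals")
  gi <- rhdf5::h5read(path, "grid_idx")
  schm <- rhdf5::h5read(path, "schedule")
  gs <- as.numeric(rhdf5::h5read(path, "grid_spec"))
  schedule <- make_schedule(nrow(schm), pattern = "custom",
                            fa_deg = schm[, 1], te_ms = schm[, 2], tr_ms = schm[, 3])
  grid <- grid_spec(gs[1], gs[2], gs[3], gs[4], gs[5], gs[6], gs[7], gs[8],
                    exclude_t1_lt_t2s = gs[9] > 0)
  params <- tibble::tibble(
    t1_ms = p[, 1], t2s_ms = p[, 2], b1 = p[, 3],
    t1_idx = as.integer(gi[, 1]), t2s_idx = as.integer(gi[, 2])
  )
  new_dictionary(params, sig, schedule, grid, grid_axes(grid))
}

#' Export dictionary parameters as CSV
#' @param dict An `mrf_dictionary`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_dictionary_csv <- function(dict, path) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  utils::write.csv(dict$params, path, row.names = FALSE)
  invisible(path)
}
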