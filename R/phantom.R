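#' Default tissue parameter table for the digital brain phantom
#'
#' Mean and standard deviation of T1 and T2* (ms) per tissue class. Values
#' are the dictionary-matching reference means for gray matter, white
#' matter, CSF and MS lesions in adult brain at 3T.
#'
#' @return Tibble with columns `tissue`, `t1_mean_ms`, `t1_sd_ms`,
#'   `t2s_mean_ms`, `t2s_sd_ms`.
#' @export
phantom_tissue_defaults <- function() {
  tibble::tribble(
    ~tissue,  ~t1_mean_ms, ~t1_sd_ms, ~t2s_mean_ms, ~t2s_sd_ms,
    "GM",     1286,        42,        53,           2,
    "WM",     825,         51,        54,           2,
    "CSF",    3003,        224,       268,          101,
    "lesion", 1284,        152,       86,           14
  )
}

#' Digital brain phantom specification
#'
#' @param shape Length-2 integer, image dimensions (min 16 x 16).
#' @param tissue_values Tibble as returned by [phantom_tissue_defaults()];
#'   per-voxel truth is drawn from each tissue's normal distribution and
#'   clipped to `t1_clip` / `t2s_clip`.
#' @param lesion_count Number of circular WM lesions (default 2).
#' @param lesion_radius_range Length-2, lesion radius range in voxels.
#' @param b1_range Length-2 within \[0.6, 1.4\]: the smooth multiplicative
#'   B1+ field spans this range (a centered radial bump). Equal endpoints
#'   give a uniform field.
#' @param t1_clip,t2s_clip Truth clipping ranges in ms, matching the
#'   dictionary grid bounds.
#' @param seed Integer seed controlling geometry and truth draws.
#' @return Object of class `mrf_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         tissue_values = phantom_tissue_defaults(),
                         lesion_count = 2L,
                         lesion_radius_range = c(2, 4),
                         b1_range = c(0.9, 1.1),
                         t1_clip = c(100, 4000),
                         t2s_clip = c(10, 3000),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L)) {
    abort("`shape` must be two integers, each >= 16.")
  }
  req <- c("tissue", "t1_mean_ms", "t1_sd_ms", "t2s_mean_ms", "t2s_sd_ms")
  if (!all(req %in% names(tissue_values))) {
    abort("`tissue_values` must have columns tissue, t1_mean_ms, t1_sd_ms, t2s_mean_ms, t2s_sd_ms.")
  }
  if (any(tissue_values$t1_mean_ms <= 0) || any(tissue_values$t2s_mean_ms <= 0) ||
      any(tissue_values$t1_sd_ms < 0) || any(tissue_values$t2s_sd_ms < 0)) {
    abort("tissue means must be positive and sds non-negative.")
  }
  if (any(b1_range < 0.6 - 1e-9) || any(b1_range > 1.4 + 1e-9) ||
      b1_range[1] > b1_range[2]) {
    abort("`b1_range` must be increasing and lie within [0.6, 1.4].")
  }
  structure(
    list(shape = shape, tissue_values = tissue_values,
         lesion_count = as.integer(lesion_count),
         lesion_radius_range = as.numeric(lesion_radius_range),
         b1_range = as.numeric(b1_range),
         t1_clip = as.numeric(t1_clip), t2s_clip = as.numeric(t2s_clip),
         seed = as.integer(seed)),
    class = "mrf_phantom_spec"
  )
}

#' Generate a digital brain phantom with ground truth
#'
#' Builds a single axial-slice phantom from concentric regions: an elliptical
#' brain outline whose outer ribbon is gray matter, a white-matter interior,
#' a central CSF core, and circular MS-like lesions placed only inside white
#' matter. Per-voxel T1/T2* ground truth is drawn from each tissue's normal
#' distribution and clipped to the dictionary range; the B1+ field is a
#' smooth radial map spanning `b1_range`.
#'
#' @param spec An `mrf_phantom_spec`.
#' @return Object of class `mrf_phantom`: list with `label_map` (X x Y
#'   integer, 0 = background, 1 = GM, 2 = WM, 3 = CSF, 4 = lesion),
#'   `t1_truth`, `t2s_truth` (ms; 0 outside the brain), `b1_truth`, the
#'   label legend `labels`, and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "mrf_phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]
  xs <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  ys <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  gx <- matrix(xs, nx, ny)
  gy <- matrix(ys, nx, ny, byrow = TRUE)
  # elliptical radius, 1 at the brain boundary
  r <- sqrt((gx / 0.92)^2 + (gy / 0.82)^2)

  labels <- c(GM = 1L, WM = 2L, CSF = 3L, lesion = 4L)
  lab <- matrix(0L, nx, ny)
  lab[r <= 1] <- labels["GM"]        # cortical ribbon (outer shell)
  lab[r <= 0.78] <- labels["WM"]     # interior
  lab[r <= 0.18] <- labels["CSF"]    # ventricular core

  with_seed(spec$seed, {
    # lesions: circles fully inside WM
    wm_idx <- which(lab == labels["WM"], arr.ind = TRUE)
    placed <- 0L; tries <- 0L
    while (placed < spec$lesion_count && tries < 200L) {
      tries <- tries + 1L
      ctr <- wm_idx[sample.int(nrow(wm_idx), 1L), ]
      rad <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      d <- sqrt((row(lab) - ctr[1])^2 + (col(lab) - ctr[2])^2)
      disc <- d <= rad
      if (all(lab[disc] == labels["WM"])) {
        lab[disc] <- labels["lesion"]
        placed <- placed + 1L
      }
    }
    if (placed < spec$lesion_count) {
      warn("could not place all requested lesions inside white matter.")
    }

    tv <- spec$tissue_values
    t1 <- matrix(0, nx, ny); t2s <- matrix(0, nx, ny)
    for (i in seq_len(nrow(tv))) {
      code <- labels[[tv$tissue[i]]]
      vox <- which(lab == code)
      if (!length(vox)) next
      t1[vox] <- pmin(pmax(rnorm(length(vox), tv$t1_mean_ms[i], tv$t1_sd_ms[i]),
                           spec$t1_clip[1]), spec$t1_clip[2])
      t2s[vox] <- pmin(pmax(rnorm(length(vox), tv$t2s_mean_ms[i], tv$t2s_sd_ms[i]),
                            spec$t2s_clip[1]), spec$t2s_clip[2])
    }
    # keep truths physically consistent with the dictionary's exclusion rule
    bad <- t1 > 0 & t1 < t2s
    t2s[bad] <- t1[bad]
  })

  # smooth radial B1+ bump: b1_max at center falling to b1_min at the edge
  b1 <- spec$b1_range[2] - (spec$b1_range[2] - spec$b1_range[1]) * pmin(r, 1)^2
  b1[lab == 0L] <- 0

  structure(
    list(label_map = lab, t1_truth = t1, t2s_truth = t2s, b1_truth = b1,
         labels = labels, spec = spec),
    class = "mrf_phantom"
  )
}

#' @export
print.mrf_phantom <- function(x, ...) {
  tab <- table(factor(x$label_map, levels = c(0L, x$labels),
                      labels = c("background", names(x$labels))))
  cat(sprintf("<mrf_phantom> %d x %d\n", nrow(x$label_map), ncol(x$label_map)))
  print(tab)
  invisible(x)
}

#' Binary tissue masks from a phantom
#' @param phantom An `mrf_phantom`.
#' @return Named list of X x Y binary matrices (`GM`, `WM`, `CSF`, `lesion`,
#'   `brain`).
#' @export
phantom_masks <- function(phantom) {
  stopifnot(inherits(phantom, "mrf_phantom"))
  lab <- phantom$label_map
  masks <- lapply(phantom$labels, function(code) (lab == code) + 0L)
  masks$brain <- (lab != 0L) + 0L
  masks
}

#' Render a baseline stack from phantom ground truth
#'
#' Simulates each in-brain voxel's fingerprint from its ground-truth
#' (T1, T2*, B1+) with the Bloch recursion, L2-normalizes it, and adds noise
#' calibrated so that the expected per-voxel SNR (matched-signal energy over
#' noise energy, in dB) equals `target_snr_db`.
#'
#' Noise models: `"gaussian"` (white), `"student_t"` (heavy-tailed, 4 df,
#' variance-matched), `"bank"` (vectors sampled from an empirical residual
#' bank via [sample_noise()], rescaled to the target energy), `"none"`.
#'
#' @param phantom An `mrf_phantom`.
#' @param schedule An `mrf_schedule`.
#' @param noise Noise model (see Details).
#' @param target_snr_db Expected per-voxel SNR in dB (ignored for `"none"`).
#' @param bank An `mrf_noise_bank`, required for `noise = "bank"`.
#' @param noise_mode Sampling mode for the bank, see [sample_noise()].
#' @param seed Integer seed for the noise draws.
#' @return An `mrf_stack` whose voxel signals are unit-norm plus noise;
#'   background voxels are zero and masked out.
#' @export
render_stack <- function(phantom, schedule,
                         noise = c("none", "gaussian", "student_t", "bank"),
                         target_snr_db = 21.78, bank = NULL,
                         noise_mode = "pooled_iid", seed = 1L) {
  stopifnot(inherits(phantom, "mrf_phantom"), inherits(schedule, "mrf_schedule"))
  noise <- match.arg(noise)
  if (noise == "bank" && !inherits(bank, "mrf_noise_bank")) {
    abort("`noise = \"bank\"` requires a noise bank.")
  }
  inb <- which(phantom$label_map != 0L)
  nt <- n_timepoints(schedule)
  sig <- simulate_fingerprints(
    schedule,
    cbind(phantom$t1_truth[inb], phantom$t2s_truth[inb], phantom$b1_truth[inb])
  )
  sig <- l2_normalize_rows(sig)
  attr(sig, "zero_rows") <- NULL

  if (noise != "none") {
    # unit-norm signals: noise energy 10^(-snr/10) per voxel in expectation
    en <- 10^(-target_snr_db / 10)
    nv <- length(inb)
    with_seed(seed, {
      eps <- switch(noise,
        gaussian = matrix(rnorm(nv * nt, sd = sqrt(en / nt)), nv, nt),
        student_t = matrix(stats::rt(nv * nt, df = 4) / sqrt(2) * sqrt(en / nt),
                           nv, nt),
        bank = {
          e <- sample_noise_matrix(bank, nt, nv, mode = noise_mode)
          e * sqrt(en) / sqrt(mean(rowSums(e^2)))
        }
      )
      sig <- sig + eps
    })
  }

  d <- c(dim(phantom$label_map), nt)
  data <- array(0, d)
  flat <- matrix(data, d[1] * d[2], d[3])
  flat[inb, ] <- sig
  baseline_stack(array(flat, d), brain_mask = (phantom$label_map != 0L) + 0L)
}
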