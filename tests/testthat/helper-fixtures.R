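# Shared small fixtures, built in code at test time.

# default 35-point schedule
fix_schedule <- function() make_schedule()

# small dictionary covering brain-tissue values: T1 600-2000 ms, T2* 40-200 ms,
# 2% grids, single B1+ level -> 61 x 82 = 5002 entries
fix_grid <- function(increment_frac = 0.02) {
  grid_spec(600, 2000, 40, 200, increment_frac,
            b1_min = 1, b1_max = 1, b1_step = 0.05)
}

fix_dictionary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dictionary(fix_schedule(), fix_grid())
    cache
  }
})

# tiny dictionary for fast structural tests: 6 x 7 grid = 42 entries
fix_tiny_dictionary <- function() {
  generate_dictionary(
    fix_schedule(),
    grid_spec(800, 1200, 50, 90, 0.08, b1_min = 1, b1_max = 1, b1_step = 0.1)
  )
}

# synthetic residual bank: white Gaussian noise at the given SNR for
# unit-norm 35-point signals
fix_gaussian_bank <- function(snr_db = 20, n = 500, nt = 35, seed = 101) {
  en <- 10^(-snr_db / 10)
  res <- mrfepi:::with_seed(seed, matrix(rnorm(n * nt, sd = sqrt(en / nt)), n, nt))
  noise_bank_from_residuals(res, sprintf("synthetic-gaussian-%gdB", snr_db))
}

# small regressor spec used by training tests (the full-width architecture is
# exercised structurally; training tests use a narrower variant of the same
# topology to stay desk-scale)
fix_regressor_spec <- function(variant = "WPDaCNN") {
  regressor_spec(backbone_channels = c(32L, 64L, 128L), variant = variant)
}
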