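# mrfepi

Quantitative T1/T2\* mapping for magnetic resonance fingerprinting with an
echo-planar readout (MRF-EPI), in R.

An MRF-EPI scan acquires a short train of baseline images per slice (35
here) under pseudo-randomly varying pulse parameters, so each voxel traces a
characteristic signal evolution — its *fingerprint* s(T1, T2\*, B1+). The
classic reconstruction simulates a dictionary of fingerprints from the Bloch
equations over a dense parameter grid and assigns each voxel the entry
maximizing the inner product ⟨s_scan, s_dict⟩ (cosine similarity on
unit-norm signals). That is accurate but slow and storage-hungry. This
package implements both the reference reconstruction and a two-stage learned
replacement:

* **Stage I** — a 1D residual-learning denoising CNN (DnCNN): 34 convolution
  layers (kernel 3, 64 channels, batch-norm) that predict the noise n̂ of a
  fingerprint; the denoised signal is x − n̂. Trained on simulated
  fingerprints corrupted by residuals sampled from an empirical noise bank
  (scan minus matched dictionary signal, temporal order discarded), with
  loss 10000 · mean((n − n̂)²).
* **Stage II** — a gamma-weighted pyramidal dual-path CNN with multi-head
  self-attention (WPDaCNN): a shared 3-block backbone (kernels 17/11/7,
  channels 128/256/512) feeding per-parameter paths; at each scale,
  8-head scaled dot-product attention softmax(QKᵀ/√d_s)V enters through a
  learnable gate Y = γ·X_attn + X, and per-scale heads are combined with
  learnable scale weights. Loss: mean|y − ŷ| + 100 · mean(|y − ŷ|/y).
  Ablations PDCNN / DCNN / SCNN included.

Everything runs on synthetic data: a digital brain phantom (GM/WM/CSF +
MS-like lesions with per-tissue T1/T2\* ground truth) renders baseline
stacks at controllable SNR, so the full pipeline is testable without patient
scans. Agreement metrics (MAPE, ICC(A,1), Bland–Altman) and NIfTI/HDF5 I/O
are included. See `vignettes/mrfepi-methods.Rmd` for the model details and
the package's design decisions — including why T1 is only weakly encoded
under long-TR spoiled schedules and what that implies for noisy data.

## Worked example

```r
library(mrfepi)

# acquisition schedule and a tissue-range dictionary (2% geometric grids)
sch  <- make_schedule()                      # 35 pts, FA 34-86, TE 21-81.5, TR 3530-6570
dict <- generate_dictionary(
  sch, grid_spec(600, 2000, 40, 200, 0.02, b1_min = 1, b1_max = 1, b1_step = 0.05)
)
dict
#> <mrf_dictionary> 5002 entries x 35 time points
#>   T1 600-1968.62 ms | T2* 40-198.918 ms | B1+ 1-1

# digital phantom rendered at 20 dB, matched against the dictionary
ph    <- make_phantom(phantom_spec(shape = c(32, 32), b1_range = c(1, 1), seed = 11))
stack <- render_stack(ph, sch, noise = "gaussian", target_snr_db = 20, seed = 13)
matched <- match_stack(stack, dict)
matched
#> <mrf_match> 32 x 32 maps, 0 unmatched voxels

# evaluate the matched T2* map against ground truth, per tissue
truth <- parametric_maps(ph$t1_truth, ph$t2s_truth)
report <- evaluate_maps(truth, matched, phantom_masks(ph)[c("GM", "WM", "lesion")])
dplyr::select(tidy(report), tissue, parameter, n_voxels, mape_pct, icc)
#> # A tibble: 6 x 5
#>   tissue parameter n_voxels mape_pct     icc
#>   <chr>  <chr>        <int>    <dbl>   <dbl>
#> 1 GM     T1             240    47.5  0.00363
#> 2 GM     T2*            240     4.37 0.498
#> 3 WM     T1             286    70.8  0.00362
#> 4 WM     T2*            286     4.48 0.457
#> 5 lesion T1              58    47.3  0.0450
#> 6 lesion T2*             58     7.50 0.860
```

The asymmetry in that table is the central physical fact of this signal
model: at 20 dB, inner-product matching recovers T2\* to a few percent but
T1 only very coarsely — with repetition times of 3.5–6.5 s, longitudinal
recovery is nearly complete every TR and the fingerprint carries little T1
information (the vignette quantifies this). Denoising (stage I) sharpens
T2\* further; no reconstructor can rescue T1 at this SNR under this model.

Training the learned pipeline:

```r
bank <- noise_bank_from_residuals(
  matrix(rnorm(2000 * 35, sd = sqrt(10^(-20/10) / 35)), 2000, 35)
)                                            # synthetic 20 dB residual bank
den <- train_denoiser(dict, bank,
                      stage1_config(batch_size = 25, epochs = 30, seed = 5),
                      denoiser_spec(depth_middle = 8, channels = 32))
reg <- train_regressor(dict, split_by_increment(dict, 2),
                       regressor_spec(backbone_channels = c(32, 64, 128)),
                       stage2_config(batch_size = 64, epochs = 60, seed = 5))
maps <- predict_two_stage(den, reg, stack)   # T1/T2* maps in ms
```

On the held-out half of the 2% dictionary (the entries *not* in the 4%
training sub-grid), this desk-scale WPDaCNN reaches ~0.5% MAPE for both T1
and T2\* on clean fingerprints; the denoiser lifts held-out SNR from 20 dB
to ~32 dB. The `scripts/acceptance.R` run prints both numbers.

A YAML-driven pipeline (`run_pipeline()`) and a thin CLI
(`inst/cli/mrfepi.R`, subcommands `make-schedule`, `simulate-dict`,
`make-phantom`, `match`, `extract-noise`, `train-denoiser`,
`train-regressor`, `predict`, `evaluate`, `run`) chain the stages with
per-artifact manifests.

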