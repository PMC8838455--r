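---
title: "Methods: two-stage learned reconstruction for MRF-EPI relaxometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage learned reconstruction for MRF-EPI relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Magnetic resonance fingerprinting (MRF) with an echo-planar readout acquires a
short train of baseline images — here 35 per slice — while the pulse
parameters (flip angle, echo time, repetition time) vary from time point to
time point. Every voxel therefore traces a characteristic signal evolution,
its *fingerprint*, jointly determined by the tissue's longitudinal relaxation
time T1, its effective transverse relaxation time T2\*, and the local
flip-angle efficiency B1+. The classic reconstruction simulates a dictionary
of fingerprints over a dense (T1, T2\*, B1+) grid and assigns each voxel the
parameters of the dictionary entry with the largest inner product against the
measured signal. That is accurate but slow (minutes per slice) and requires
storing hundreds of thousands of simulated signals per slice.

`mrfepi` implements that reference reconstruction and a two-stage learned
replacement:

* **Stage I** — a one-dimensional residual-learning denoising CNN (a 1D
  DnCNN) that predicts the noise component of a fingerprint; the denoised
  signal is the input minus the prediction.
* **Stage II** — a gamma-weighted pyramidal dual-path CNN with multi-head
  self-attention (WPDaCNN) that regresses T1 and T2\* (in ms) directly from
  the denoised fingerprint, with PDCNN / DCNN / SCNN ablations.

A digital brain-phantom generator supplies fully synthetic test data with
known ground truth, so the whole pipeline is testable without patient scans.

## Signal model

The simulator tracks only longitudinal magnetization between excitations
(ideal spoiling: transverse coherence is assumed fully dephased before each
pulse). Starting from thermal equilibrium `Mz(1) = m0`, time point `i` with
effective flip angle `alpha_i = b1_eff * fa_i` produces the echo

```
s_i = Mz(i) * sin(alpha_i) * exp(-TE_i / T2*)
```

after which the longitudinal component recovers over the remainder of the
repetition time:

```
Mz(i+1) = m0 + (Mz(i) * cos(alpha_i) - m0) * exp(-TR_i / T1)
```

The output fingerprint is the magnitude signal. A single pass through the
schedule is simulated by default; `n_prep_cycles` adds un-recorded
preparation passes for steady-state variants. Inversion or other preparation
pulses are not modeled.

The default schedule interpolates flip angle 34–86°, TE 21–81.5 ms and TR
3530–6570 ms linearly over the 35 time points. Exact per-time-point values of
the clinical protocol are site-specific and not public; any schedule can be
supplied as a 3-column text file (`read_schedule()`).

### T1 encoding under long-TR schedules

A consequence of this model that shapes everything downstream: with TR
between 3.5 and 6.5 s and brain T1 between 0.6 and 2 s, longitudinal recovery
within each TR is nearly complete (`exp(-TR/T1)` is 0.003–0.17), so the
fingerprint depends only weakly on T1. Numerically, a 5% change in T1 moves
the unit-norm fingerprint by ~1e-4 (L2), while a 5% change in T2\* moves it
by ~1.3e-2 — a conditioning ratio of roughly 150. Two measurable
consequences, which the test suite demonstrates rather than hides:

* noise-free inner-product matching on a 2% grid recovers T2\* to well under
  1% but T1 only to ~8% (adjacent T1 entries are nearly collinear);
* at realistic noise (~20 dB), no estimator can recover T1 accurately from a
  single fingerprint — the information is simply not in the signal under
  this model. T2\* remains well determined.

Clinical MRF-EPI implementations retain T1 sensitivity through
slice-interleaved excitation history and preparation details that are not in
the public protocol description (this is also why per-slice dictionaries are
used clinically). Within this package's explicit signal model the weak T1
encoding is a property of the physics, and the evaluation reports it as
such.

## Dictionaries and splits

Relaxation grids are geometric (`make_geometric_grid()`): a 2% grid starting
at 100 ms runs 100, 102, 104.04, … up to the largest value below the bound.
The default grid spans T1 100–4000 ms, T2\* 10–3000 ms (entries with
T1 < T2\* excluded as unphysical) and B1+ 0.6–1.4 in steps of 0.05.
Fingerprints are L2-normalized at storage time since the inner-product match
is scale-free.

Two train/validation divisions probe a learned regressor in opposite ways:

* `split_by_range()` trains on T1 ∈ [500, 2500] ms and T2\* ∈ [50, 1500] ms
  and validates on everything outside — an *extrapolation* probe expected to
  fail (the model has never seen those signal shapes);
* `split_by_increment()` trains on every k-th grid value of both axes
  (yielding an effective `(1+f)^k - 1` increment) and validates on the
  unsampled entries — an *interpolation* probe expected to succeed.

## Stage I: the 1D denoiser

Architecture: `conv(3, pad 1, 64) + ReLU`, then 32 units of
`conv + batch-norm + ReLU`, then a final `conv` to one channel (34
convolution layers in the reference configuration; depth and width are
configurable). The model predicts the *residual* (noise), and
`denoise_signal()` subtracts it from the input.

Training corrupts each dictionary fingerprint with noise drawn from an
empirical *noise bank* — residuals between scanned and matched signals,
pooled with their temporal order discarded (`pooled_iid`, the default) or
re-used as permuted whole vectors (`permuted_vector`). The loss is the L2
error scaled by 10,000 (readable magnitudes for unit-norm signals); the
optimizer is Adam at 0.01 with a 5% learning-rate decay per epoch, batch 500,
100 epochs in the reference configuration, and the checkpoint with the
lowest *training* loss is kept — deliberately no validation split at this
stage, which the function flags with a warning.

Two initialization details matter in practice and are deliberate:

* the final convolution is initialized near zero, so the untrained network
  starts at the zero-prediction baseline instead of predicting large spurious
  residuals — without this, most of a short training budget is spent
  shrinking the output scale;
* batch-norm running statistics are frozen into the selected checkpoint, so
  inference is deterministic.

A useful calibration: for fingerprints on this dictionary's 2-parameter
manifold, the *optimal linear* (affine) denoiser already achieves a
15–17 dB SNR gain at 20 dB input — the manifold is low-dimensional and
nearly flat. The desk-scale CNN (depth 8, 32 channels, 30 epochs over 2,000
signals) reaches ~12 dB; the remaining gap is training budget, not model
class.

## Stage II: the pyramidal attention regressor

A shared backbone of three convolution blocks (kernel 17/11/7, channels
128/256/512 in the reference configuration, each `conv + ReLU +
dropout(0.2)`, valid convolutions, stride 1) yields feature maps at three
scales — lengths 19, 9 and 3 for a 35-point input. T1 and T2\* each have
their own output path. Within a path, each scale passes through:

1. multi-head self-attention (8 heads; per-head `d_s x d_s` query/key/value
   projections of a contiguous channel slice; scaled dot-product
   `softmax(Q K' / sqrt(d_s)) V`; concatenated heads projected by `W^O`),
2. a gated residual `Y = gamma * Xa + X` with `gamma` learnable and
   initialized to 0 (the attention branch starts closed, so training begins
   from the plain pyramid),
3. flatten → FC(128) → ReLU → FC(3).

The three per-scale 3-vectors are combined with learnable scale weights
(initialized 1/3 so the initial combination is an average), and a final FC
emits the parameter value in ms. Ablations: PDCNN removes attention and all
gammas (plain sum over scales); DCNN keeps only the deepest scale; SCNN is
DCNN with a single path emitting both values.

The loss adds L1 (ms) and 100 × mean absolute percentage error; the MAPE
term balances T1 (hundreds to thousands of ms) against T2\* (tens of ms).
Targets are regressed in raw milliseconds; the final-layer bias is
initialized to the training-set target means. Checkpoint selection uses the
lowest validation loss by default. For *extrapolation* probes
(`split_by_range()`), that rule would early-stop on the out-of-range loss —
i.e. on the very failure being measured — so `stage2_config(selection =
"final")` keeps the fully trained model instead; this mirrors how the
full-scale train/validation contrast is reported after complete training.
Dropout is disabled at inference, so prediction is bit-reproducible.

### Input whitening

Because of the 150:1 conditioning ratio described above, the raw fingerprint
is a pathological regression input: gradient descent finds the T2\*
directions immediately and effectively never moves along the T1 directions.
Stage II therefore prepends a *fixed* ZCA-whitening transform computed from
the training split: `x -> W (x - mu)` with
`W = U diag(1/sqrt(lambda + lambda_max / cap^2)) U'`. The gain cap bounds the
amplification of near-null directions. This is an architecture choice, part
of the stored model, applied identically at training and inference. The cap
trades T1 learnability on clean signals (higher cap = stronger equalization)
against noise amplification on measured signals (the T1-informative
directions sit *below* the noise floor at clinical SNR, so whatever
amplifies them amplifies noise more). The package default (`whiten_gain_cap
= 1000`) favors the clean-signal regime the stage is trained in; predictions
are clamped to the trained target range (as dictionary matching is bounded
by its grid) so off-distribution inputs degrade to range edges rather than
diverging.

## The digital phantom

`make_phantom()` builds a single axial slice from concentric regions — an
elliptical brain whose outer ribbon is gray matter, white-matter interior,
central CSF core — plus circular MS-like lesions placed wholly inside white
matter. Per-voxel ground truth is drawn from per-tissue normal distributions
(defaults: T1 1286±42 / 825±51 / 3003±224 / 1284±152 ms and T2\* 53±2 /
54±2 / 268±101 / 86±14 ms for GM / WM / CSF / lesion — adult brain at 3T as
estimated by dictionary matching), clipped to the dictionary range, with
T2\* further clipped at T1 for physical consistency. The B1+ field is a
smooth radial bump (default span 0.9–1.1; set `b1_range = c(1, 1)` for a
uniform field when the dictionary holds a single B1+ level).

`render_stack()` simulates each in-brain voxel's fingerprint, normalizes it,
and adds noise calibrated so the expected per-voxel SNR
(`10 log10(signal energy / noise energy)`) hits the target, 21.78 dB by
default. Noise models: white Gaussian; variance-matched Student-t (4 df) as
a heavy-tailed bridge toward real MRI noise, which is not Gaussian; or
vectors sampled from an empirical residual bank. What the phantom does *not*
emulate: EPI distortion, partial-volume mixtures at tissue boundaries,
spatially correlated noise, coil shading, or motion — conclusions from
phantom tests transfer to real data only insofar as those effects are
secondary to voxel-wise signal fidelity.

## Evaluation

`evaluate_maps()` compares two sets of parametric maps per tissue mask and
parameter: MAPE over masked voxels, ICC(A,1) (two-way random effects,
absolute agreement, single measure — the most conservative of the common ICC
forms; the form used by the upstream statistics package is not uniquely
documented, so the conservative one is the default), and Bland–Altman
difference-vs-mean statistics with a Pearson test for proportional bias.
Masks come from `phantom_masks()` or from thresholding segmentation
probability maps at 80% of their maximum (`threshold_probability_map()`).
Per-voxel pairs are the unit of analysis for the table-style statistics;
per-region means are appropriate for subject-level agreement plots.

## Problem sizes for desk-scale verification

The test suite and the acceptance script run the full pipeline at reduced
scale, chosen once to exercise every mechanism on one CPU:

* dictionary: T1 600–2000 ms × T2\* 40–200 ms at 2% spacing, single B1+
  level (5,002 entries) — covers the GM/WM/lesion tissue ranges;
* stage I: depth 8, 32 channels, batch 25, 30 epochs over 2,000 signals,
  with a synthetic Gaussian residual bank at 20 dB;
* stage II: channels 32/64/128 (same topology and head count as the
  reference 128/256/512), batch 64, 60 epochs on an interval-2 (4%) split,
  validation capped at 500 entries per epoch for checkpoint selection with
  final metrics on the full validation set;
* extrapolation probe: a wider 6% dictionary (T1 300–4000 ms, T2\*
  20–2000 ms), range split at T1 500–2500 / T2\* 50–1500 ms, 50 epochs with
  final-epoch selection;
* phantom: 32×32, uniform B1+, 20 dB Gaussian noise.

The reference full-width configurations are exercised structurally
(construction, forward shape, layer counts) in the same suite.

## Known limitations

* T1 estimation under the long-TR spoiled model is information-limited at
  realistic SNR (see above); T1 maps from any reconstructor — matching or
  learned — are correspondingly unreliable on noisy data, and the
  evaluation reports this honestly.
* Stage II is trained on clean simulated signals only (as in the reference
  workflow); its robustness to residual noise after stage I is emergent, not
  enforced, and degrades when input whitening amplifies sub-noise-floor
  directions.
* The phantom is geometric, not anatomical; no spatial regularization or 2D
  context is used anywhere (the method is strictly voxel-wise).
* One model pair serves one acquisition schedule; clinical multi-slice
  deployments would train one pair per slice, which is a scale choice, not
  an algorithmic one (the pipeline loops over a slice manifest).
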