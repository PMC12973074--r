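---
title: "Translating scalp EEG into ventral-striatum BOLD: model, validation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating scalp EEG into ventral-striatum BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reward-related activity in the ventral striatum (VS) is visible in fMRI
but not directly in scalp EEG. During simultaneous EEG–fMRI, however, the
two modalities watch the same underlying process: oscillatory EEG sources
wax and wane, and the hemodynamic response function (HRF) turns those
power fluctuations into delayed, low-pass-filtered BOLD changes. This
package implements a group-level translation analysis: a convolutional
autoencoder learns the mapping from a multichannel EEG window to the VS
BOLD time series of the same interval, and a battery of statistical
controls asks whether the learned mapping is real (phase-randomization
surrogates), anatomically specific (control regions), robust to
upsampling (native-rate control), and functionally valid (win events
drive the prediction harder than loss events).

Because the original simultaneous recordings cannot be redistributed,
the package ships a synthetic session generator with known ground truth;
every claim the test suite makes is checked against that ground truth.

## The model

The network is an interpretable regression autoencoder. Its front end,
the *compact block*, runs `n_branches` parallel streams; each branch
applies

1. a learnable spatial filter (one weight per channel, applied at every
   time point),
2. a depthwise temporal convolution (kernel 51) acting as a band filter,
3. ReLU rectification, and
4. a second depthwise convolution (kernel 51) acting as temporal
   smoothing,

so each branch outputs an envelope-like series: "the power of one
spatially and spectrally specific source". Neither compact-block
convolution carries a bias, so the filter → band → power reading survives
training. A shared kernel-3 projection feeds a three-block encoder
(conv 3 / batch norm / GeLU / dropout 0.3 / max-pool stride 8) and a
mirrored decoder (channels reduced 4×, ×8 linear upsampling per block), a
final linear resize to the exact input length, and a 1×1 readout.

The loss is `0.9 * MSE + 0.1 * (-r)` per window (Pearson r negated so
the loss falls as prediction and target co-vary), optimized with AdamW
under a single cosine-annealed learning rate. Cross-validation is at run
level: each fold holds out one run for testing and reserves a second run
for early stopping; training stops when validation loss has exceeded its
running best for `patience` consecutive epochs while training loss kept
falling.

At full scale the defaults follow the study protocol: 62 channels, 16
branches, encoder width 128, 160 s windows at 100 Hz (62 × 16 000
inputs), learning rate 3e-5, weight decay 3e-4, batch 32, T_max 50,
patience 15, 1000 surrogates, 20 folds.

## The synthetic generator

`synthetic_config()` emulates a four-run gambling session: 62-channel EEG
at 100 Hz, 4 runs × 100 trials (10 s each: feedback at +5 s, 2 s outcome
display), 530 BOLD volumes per run at TR = 2 s. Each planted source is a
band-limited Gaussian carrier (default 10 Hz ± 2 Hz) behind a unit-norm
spatial pattern; its amplitude is multiplied by `win_gain` (2) or
`loss_gain` (0.5) for 2 s after each feedback onset, with exactly half
wins and half losses per run. The target ROI's BOLD is the HRF-convolved
`envelope^2` of source 1 (the squared Hilbert envelope; the exponent adds
the mild nonlinearity that separates the deep model from a linear
readout), delayed 6 s, sampled at the TR, noised and z-scored. Control
ROIs ("VC", "PMC", "STN") receive `control_coupling` (0.15) times the
standardized clean drive plus independent unit noise.

Noise levels were fixed once at values a practitioner would call
realistic: per-channel 1/f background of unit SD (slope 1), white sensor
noise of SD 0.5, source baseline amplitude 2 (so the source is below the
noise floor on any single channel but dominates the channel covariance,
as posterior alpha does in real recordings), and `bold_noise_sd = 1` in
units of the standardized clean drive, which puts the noise ceiling —
`oracle_envelope_r()`, the correlation between the regenerated clean
drive and the noisy BOLD — near 1/sqrt(2) ≈ 0.71.

What the generator does *not* emulate: MR gradient and
ballistocardiographic artifacts, volumetric fMRI, head motion,
non-stationary source frequencies, and spatially correlated sensor
noise. Passing tests therefore demonstrate that the pipeline recovers a
planted spatio-spectral coupling under realistic SNR — not that it would
survive the artifact structure of raw scanner EEG, which the upstream
cleaning steps (out of scope here) are responsible for.

## Desk-scale profile

The test suite and the shipped analysis run a reduced profile chosen for
a single CPU: 16 channels, 4 branches, encoder width 32, a 50 Hz common
rate (the envelope information lives far below 25 Hz), 160 s windows,
and sessions of 20 minutes (recovery experiment: 4 × 5-minute runs) or
an hour (group experiment: 12 × 5-minute runs, 10 folds). Problem sizes
were set so the whole suite and the acceptance script each finish in
tens of minutes.

Training at this scale has a few hundred optimizer steps where the
full-scale protocol has many thousands, and three choices compensate —
all exposed as `train_config()` options and all documented here because
they are departures the small compute budget forces:

* **Learning rate 3e-3** (vs 3e-5 at full scale): a few hundred steps
  must do the work of thousands.
* **Data-driven warm start of the compact block**
  (`data_driven_init = TRUE`): spatial filters start at the leading
  principal components of the training-run channel covariance, and each
  branch's band kernel starts as a windowed sinusoid at the frequency
  where that component's spectrum most exceeds the average component
  spectrum. This is unsupervised (no target signal is touched, and only
  the fold's training runs are used), in the spirit of PCA/ICA-seeded
  EEG decoders; with random initialization the spectral search consumes
  more steps than a CPU-scale run has. The compact block then trains at
  a reduced rate (`compact_lr_mult = 0.02`) so gradient noise does not
  overwrite the warm start before the encoder–decoder has learned to use
  it.
* **Tail weight averaging** (`tail_average_epochs`): the returned
  weights are the average over the last 30% of epochs, with the batch
  normalization statistics recalibrated on fresh training windows. In
  short runs the single best-validation-epoch checkpoint is a noisy
  draw (one 5-minute validation run estimates r with a standard error
  near 0.07); averaging the cosine tail removes that lottery. With
  `tail_average_epochs = 0` the implementation returns the
  best-validation-epoch weights, selected by validation correlation
  smoothed over five epochs — validation *loss* is nearly flat in
  prediction scale around r ≈ 0 and cannot rank checkpoints.

With this profile the trained translator reaches held-out correlations
of roughly 0.3–0.5 — with occasional weaker seeds — against a noise
ceiling of ≈ 0.71 on the 20-minute recovery sessions (the suite prints
the per-seed values), and the
group-level experiment reproduces the qualitative result pattern — deep
model above the linear baseline, target region above every control
region, win beta above loss beta — with large margins. A diagnostic
worth recording: a ridge readout of the warm-started compact features
with explicit lags reaches r ≈ 0.62–0.65 on the same data, so the
desk-scale gap to the ceiling is an optimization budget limit of the
deep decoder, not a missing-information limit.

## Numerical and design choices

* **Alignment.** `align_pair()` advances the EEG by `delay_s` (6 s) so
  that BOLD at t is paired with EEG at t − 6 s; both series are trimmed,
  never padded. BOLD is cubic-spline interpolated to the common rate
  (`method = "linear"` is the fallback switch); EEG is anti-alias
  filtered (8th-order Butterworth at 0.8 of the target Nyquist) before
  integer decimation. After alignment, the HRF-convolved true drive
  aligns with the BOLD at lag zero to one-sample precision; the raw
  envelope leads by the HRF peak delay (≈ 5 s).
* **Windows** are drawn uniformly with replacement, fresh each epoch;
  z-scoring is per run, before windowing.
* **Normalization** in the encoder/decoder is batch normalization over
  (time, batch) per channel, with an instance-normalization switch.
* **Correlation conventions.** Zero-variance inputs yield r = 0 (with a
  warning in `pearson_r()`); the correlation loss is computed per
  window and averaged over the batch.
* **Phase randomization** preserves DC and Nyquist bins and imposes
  Hermitian symmetry, so surrogates are real with exactly the original
  amplitude spectrum. The permutation test is one-sided on positive r
  with add-one correction, `p = (1 + #{null >= obs}) / (1 + n)`; the
  full-scale default is 1000 surrogates, the desk profile uses 200.
* **Downsampling control** decimates the prediction by TR-bin means; a
  prediction that holds each volume's value across its TR decimates back
  to the native series exactly.
* **Specificity** replaces a voxelwise whole-brain regression with its
  ROI-level analogue: per ROI, the correlation with the prediction and
  the prediction's OLS coefficient with the run's HRF-convolved event
  regressors as nuisance covariates.
* **Interpretation.** Branch importance is ablation-based (zero one
  branch's compact output, measure the held-out correlation drop) —
  a direct measure of contribution. Spatial filters are projected
  through the evaluation-data channel covariance (`C_x w`) to obtain
  forward-model patterns; frequency profiles multiply the band kernel's
  magnitude response by the amplitude spectrum of the spatially filtered
  signal on the kernel's DFT grid (resolution fs/51 ≈ 1 Hz at 50 Hz).
  Across folds, profiles are averaged by rank with sign alignment,
  since spatial patterns are sign-ambiguous.
* **Degenerate inputs.** Constant channels z-score to zeros; collinear
  event designs and rank-zero feature matrices raise classed errors
  (`eegbold_degenerate_input`); a non-finite training loss aborts with
  the epoch index.

## Known limitations

* The full-scale configuration (62 channels, encoder 128, 160 s windows
  at 100 Hz, thousands of steps) is supported by the same code paths but
  is not exercised by the suite; only the reduced profile is routinely
  validated end to end.
* The generator's single-lag, single-source coupling is simpler than
  real EEG–BOLD physiology (multiple sources, state-dependent coupling,
  motion); conclusions about real data rest on the upstream literature,
  not on these simulations.
* The encoder–decoder at desk scale stops well short of the noise
  ceiling (see above); reported correlations should be read relative to
  the printed oracle values, not as absolute performance.
* Early stopping rarely fires under the desk profile (the patience
  window is a large fraction of the budget); it is exercised directly by
  unit tests instead.
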