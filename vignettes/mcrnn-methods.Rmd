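---
title: "Multi-scale convolutional recurrent networks for resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale convolutional recurrent networks for resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Psychiatric diagnoses (major depressive disorder, bipolar disorder,
schizophrenia) rest on clinical interviews; resting-state EEG (rsEEG) is an
inexpensive candidate source of objective biomarkers. This package
implements an end-to-end classification pipeline that learns directly from
rsEEG time series — no hand-crafted frequency-band features — and then
interrogates the trained model: which channels carry the discriminative
signal, and how do the learned representations arrange the disorders on a
low-dimensional spectrum.

The pipeline has five stages, each with a programmatic surface and a CLI
subcommand: cohort simulation (`simulate_cohort()`), preprocessing
(`preprocess_cohort()`), model training (`fit_mcrnn()`), subject-level
leave-one-out evaluation (`loocv()`/`confusion()`), and interpretation
(`occlusion_importance()`, `extract_penultimate()`, `embed_2d()`).

# The network

Inputs are one-second epochs: 64 channels x 250 samples (250 Hz). The
architecture is:

* three parallel 1-D convolution branches along time, kernel lengths 2, 4
  and 8 (each kernel spans all 64 channels), 32 filters each, stride 1,
  same-padding, ReLU. Concatenation gives a 250 x 96 feature map.
* temporal max-pooling with window and stride 3 (non-overlapping),
  truncating the remainder: 83 x 96.
* a single unidirectional GRU with 32 hidden units over the 83 steps.
* the time-average of all GRU hidden states (a 32-vector), a fully
  connected layer with 32 units and ReLU, a linear map to the classes and
  softmax.

Chosen conventions the architecture description leaves open, each fixed and
oracle-tested:

* **Padding.** Same-padding is forced by the printed 250-point concat
  shape; for even kernels the extra pad sample is on the left.
* **Nonlinearity.** ReLU after every convolution branch and after FC-32.
* **GRU variant.** Update gate `z`, reset gate `r`, candidate
  `n = tanh(Wx x + Wh (r * h) + b)` (reset applied to the recurrent term),
  `h' = (1 - z) h + z n`; single layer, zero initial state.
* **Pooling ties.** The earliest sample in a window wins (relevant only
  for exactly equal values).
* **Initialization.** Seeded Glorot-style uniform draws,
  `U(-sqrt(6/(fan_in+fan_out)), +...)`; biases zero.
* **Dropout placement.** After the conv concat (rate 0.5), on the GRU
  inputs with one mask per sample shared across timesteps (0.3), and after
  FC-32 (0.5); active only during training.
* **"Penultimate" feature.** Both 32-d candidates are exposed:
  `extract_penultimate()` returns the time-averaged GRU state by default
  (`layer = "gru_avg"`) and the FC-32 activation with `layer = "fc"`.

The forward and backward passes are written in vectorised R over compiled
(RcppArmadillo) kernels for the convolution GEMMs, max-pooling and the GRU
recurrence. The batched training/prediction path computes in single
precision (standard practice for network training, and about twice as fast
on CPU BLAS); the exported single-epoch operations (`multi_scale_conv()`,
`gru_forward()`, ...) run the same templated kernels in double precision
and are the reference surface: the backward pass is verified against
central finite differences, and every forward operation against
brute-force loop implementations in the test suite. The two precisions
agree to about 1e-6 on unit-scale inputs.

# Training regime

Adam on the softmax cross-entropy plus an L1+L2 penalty (1e-4 each) on the
GRU input kernel. Batch size 512; learning rate 0.001 with inverse-time
decay `lr0 / (1 + 0.01 * epoch)` (the era's standard "decay" semantics; a
multiplicative mode is available via `decay_mode`). The validation set is
20% of the training samples; training stops when the validation loss has
not reached a new minimum for 50 consecutive epochs or at 1000 epochs, and
the weights with the highest validation *accuracy* are kept (loss stops,
accuracy selects — both monitors implemented exactly).

Two deliberate open points:

* **Validation split level.** The default draws the 20% at the *epoch*
  level, literally "20% of the training samples". Epochs of one subject
  then appear on both sides, which inflates validation accuracy; a
  `val_split_level = "subject"` mode holds out whole subjects and is the
  honest choice when validation scores are reported.
* **Class imbalance.** No reweighting by default (the cohort sizes
  72/138/70/47 are used as-is); `class_weights = "inverse_frequency"` is
  available.

Evaluation is subject-level leave-one-out: one fold per subject, the fold's
validation split drawn inside the remaining subjects, and the held-out
subject predicted by averaging its epochs' probability vectors (argmax,
ties to the lowest class index). A membership audit asserts on every fold
that no held-out epoch leaks into training or validation. Confusion
matrices count subjects; epoch-level accuracy is reported separately and
labelled as such, since the two can differ substantially.

# The synthetic cohort generator

Clinical recordings cannot be redistributed, so the package ships a
generator that emulates the study regime: 64-channel 10/20 montage
(CPz-referenced by construction), 1 kHz sampling, 300-s sessions, cohort
sizes BP = 72, MDD = 138, SZ = 70, NC = 47, units of microvolts.

Signal model per channel: `1/f^alpha` Gaussian background (alpha = 1,
RMS 10 uV) with the spectrum flattened below a 1 Hz knee, plus a 1 uV white
floor, plus class-specific narrow-band components (Gaussian spectral
window) on target channels only. The knee exists because unbounded `1/f`
low-frequency power makes one-second epoch variances erratic in a way real
band-limited scalp EEG is not. Reproducibility: each subject's stream is
`master_seed + 100000 * class_code + subject_index`, so cohorts can grow
without reshuffling existing subjects.

Default class signatures (amplitudes in uV RMS):

| class | component | channels | rationale |
|---|---|---|---|
| NC | none | — | background only |
| SZ | 40 Hz, bw 4, amp 12 | O1, P3 | left-posterior gamma enhancement; gamma-band abnormalities are among the most replicated EEG findings in schizophrenia |
| MDD | 25 Hz, bw 4, amp 12 | Fp1, F8 | frontal beta component |
| BP | 25 Hz, bw 4, amp 7 | Fp1, F8 | *the same* component as MDD at lower amplitude — the two classes are deliberately confusable, mirroring the clinical MDD/BP overlap |

Why these bands: the convolution kernels span at most 8 samples (32 ms) at
250 Hz. Empirically the network separates planted components above ~20 Hz
reliably at these amplitudes, while a 10 Hz alpha component over a `1/f`
background is not learnable at desk-scale cohort sizes even at much higher
amplitude — an honest property of short-kernel architectures with tens of
subjects rather than hundreds. An alpha-band variant is a one-liner
(`signature_component(c("O1","P3"), 10, 2, amp)`) and becomes learnable as
the cohort and training budget grow toward the study scale (327 subjects,
~300 epochs each, up to 1000 training epochs).

What the generator does *not* emulate: volume conduction and channel
covariance from a head model, non-stationarity across a session, eye/muscle
artifact morphology beyond stereotyped templates, medication or severity
covariates, inter-subject spectral variability. Passing tests on this
generator therefore demonstrate that the pipeline recovers *planted*
spatial/spectral class structure end-to-end — not that the printed clinical
accuracies would be reproduced on real patients.

Artifacts: `inject_artifacts()` superimposes Poisson-scheduled transients —
0.3-s, 300-uV frontopolar half-sine "blinks" or 0.15-s, 250-uV Hann-windowed
10 Hz bursts on random channels — both calibrated to exceed the +/-100 uV
rejection threshold after filtering.

# Preprocessing

`downsample()` (anti-alias: zero-phase order-6 Butterworth low-pass at 0.8
of the new Nyquist, then decimation), `bandpass()` 0.5-70 Hz (zero-phase
order-4 Butterworth high-pass and low-pass in cascade; a direct band-pass
at 0.002 normalized frequency is numerically fragile), `extract_epochs()`
(non-overlapping 1-s windows from sample 0; 0-based half-open indexing) and
amplitude rejection at +/-100 uV — the artifact-correction stand-in, since
the original procedure is unspecified beyond "artifacts correction". A
clean 300-s recording yields exactly 300 epochs, the top of the expected
260-300 range; the simulator's artifacts trip the threshold and lower the
count. `normalize_epochs()` z-scores each channel within each epoch by
default (raw microvolt inputs destabilize training); `none` is available.
Zero-variance channels are zeroed with a warning rather than erroring.

# Interpretation

**Occlusion.** A channel's importance is the mean drop in the true-class
probability when that channel's rows are replaced by zeros (on z-scored
data, zeros coincide with the channel mean; a `channel_mean` occluder is
provided and agrees on normalized input). Whole-channel occlusion with a
probability-drop metric is the simplest faithful reading of "discriminative
power of each EEG channel"; granularities like channel x time are out of
scope.

**Embedding.** The 32-d penultimate features of all epochs are projected to
2-D with UMAP (run through the umap-learn implementation via a small
bundled Python runner, `random_state` = seed) or PCA (`method = "pca"`,
deterministic sign convention). The UMAP fit pools all epochs, matching a
single shared map; neighborhood size shrinks automatically (with a warning)
for small inputs.

# Numerical and degenerate-input choices

* Probabilities are computed with max-subtracted softmax; losses clamp
  probabilities at 1e-12 before the log.
* Early stopping counts a validation-loss improvement only when it exceeds
  1e-6 — the forward pass computes in single precision, so smaller changes
  are numerical jitter, not progress.
* Non-finite training loss aborts with the epoch and learning rate.
* A recording shorter than one epoch gives an empty epoch set plus a
  warning; a single-class cohort refuses leave-one-out; subject-level
  validation splits retry stratification 100 times before erroring.
* EDF output quantizes to 16 bits against per-channel symmetric physical
  limits *as printed* in the 8-character header fields, so writer and
  reader agree exactly; the array container (RDS + JSON sidecar) is
  lossless.

# Desk-scale test design

The study-scale experiment (327 subjects x ~300 epochs, batch 512, up to
1000 training epochs, full leave-one-out) is configuration, not code: the
test suite and examples run reduced designs chosen for a single CPU.

* *Separability and biomarker recovery* (two-class): 8 subjects per class,
  8 one-second epochs per subject, a high-SNR planted marker (40 Hz,
  20 uV RMS on O1 + P3), batch size 16. The leave-one-out suite trains up
  to 100 epochs with patience 25; the ten biomarker-recovery repetitions
  (five cohorts x two training seeds) train a fixed 50 epochs, which is
  already sufficient for the occlusion ranking to lock onto the planted
  channels.
* *Four-class confusion structure*: default signatures, 12 subjects per
  class with 10 epochs each, one subject-level holdout (train 8 per class,
  test 4 per class), 220 training epochs, and epoch-level confusion
  counts on the held-out subjects. A desk-scale leave-one-out of a
  four-class model cannot learn (too few subjects per fold), and the
  count level of published confusion matrices is ambiguous anyway;
  epoch-level counts over held-out subjects give the stabler qualitative
  readout.

These sizes are stated here as the package's test design so that results
are interpreted at the scale they were computed.

# Known limitations

* The backbone is trained per fold from scratch; no warm starts, no
  hyperparameter search, CPU only.
* Epoch-level validation splitting (the default, kept for fidelity) leaks
  subject identity into model selection; use subject-level splits for
  honest reporting.
* The generator's independence across channels means spatial patterns are
  literal channel subsets, easier than volume-conducted sources.
* Printed clinical accuracies (68.2% four-class; 78.6-91.3% two-class) are
  properties of a private cohort and are not reproduction targets for the
  synthetic regime.
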