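---
title: "Estimating blood pressure and SpO2 from PPG: models and methods"
author: "ppgvitals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood pressure and SpO2 from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Arterial blood pressure (ABP) is measured continuously only through an
invasive arterial catheter; cuff devices are intermittent and uncomfortable.
The photoplethysmogram (PPG) — the optical blood-volume waveform that every
pulse oximeter already records — is quasi-periodic in sync with the heartbeat
and carries enough morphological information to regress the per-beat pressure
extrema: arterial systolic blood pressure (ASBP, the beat peak) and arterial
diastolic blood pressure (ADBP, the beat valley), as well as peripheral
oxygen saturation (SpO2). `ppgvitals` implements an end-to-end pipeline for
this regression problem: ICU-style waveform quality control, empirical mode
decomposition (EMD) into multichannel model inputs, an encoder-only
time-series transformer trained by masked reconstruction and personalized by
per-patient chronological fine-tuning, and device-standard compliance
evaluation (AAMI, BHS).

Because clinical waveform databases cannot ship with a package, every stage
is exercised on a synthetic cohort generator whose ground truth is known
exactly; the generator is first-class, tested code.

## Signal quality control

Raw ICU waveform records are filtered and cleaned in a fixed order:

1. **Record-level inclusion** (`filter_records`): at least 10 minutes of
   signal, both a PPG (`PLETH`) and an `ABP` channel (matched
   case-insensitively against an extensible alias table, since header
   dialects vary), and at least 17 kB on disk (17 x 1024 bytes). Every
   exclusion is logged with its reasons.
2. **Flat-part handling** (`detect_flat_runs`, `drop_or_suture`): a "flat"
   stretch is three or more consecutive equal samples (equality tolerance
   `eps = 0` by default, because digitized signals repeat exactly;
   configurable for float inputs). If flat parts cover more than 5% of
   either channel the record is discarded; otherwise the flat samples are
   removed at the same indices from all channels and the remainder is
   sutured. The 5% rule is evaluated per channel (worst channel decides) —
   the conservative reading where a joint evaluation is also defensible.
3. **Hampel filtering** (`hampel_filter`): applied to the *beat-wise* ABP
   peak and valley series (not raw samples — outliers of interest are
   per-beat artifacts), with a centered window of nominal size 100
   (half-width 50, truncated at the edges) and the standard Hampel scale
   3 x 1.4826 x MAD.
4. **Band-pass filtering** (`butterworth_bandpass`): a 4th-order Butterworth
   band-pass, 0.5–8 Hz, applied zero-phase (forward–backward) to the PPG so
   beat timing is not shifted relative to the pressure channel. The
   effective magnitude response is therefore the square of the single-pass
   design; a finite constant segment retains a slow high-pass transient of
   order 0.2% mid-signal, which is why the package's tests assert the
   analytic design response at DC (exactly zero) separately from the
   greater-than-40 dB empirical attenuation.
5. **Cycle detection** (`detect_cycles`): local maxima filtered by
   *topographic prominence* (height above the higher of the two saddles
   toward the nearest taller peaks) of at least 0.3 of the rolling 5-s
   amplitude range, with a 60/200 s refractory distance (the 200 bpm
   physiological bound); valleys are the minima between consecutive peaks.
   Topographic prominence rather than height-above-local-minimum is what
   keeps the dicrotic notch from being detected as a second beat at low
   heart rates.
6. **Segmentation and gating** (`preprocess_record`): consecutive
   non-overlapping 20-s windows (2,500 samples at 125 Hz) starting at the
   first detected cardiac cycle; a trailing partial window is dropped. A
   cycle is *anomalous* when its valley-to-valley length leaves the
   20–200 bpm band or its peak-to-valley amplitude deviates from the
   segment median by more than 3 robust sigmas; the scale estimate is
   `max(1.4826 * MAD, 2% of the median amplitude)` — the relative floor
   prevents the degenerate zero-MAD case on near-identical clean beats from
   flagging everything, while genuine motion spikes exceed the threshold by
   orders of magnitude. A segment qualifies only if both channels show at
   most 3 anomalous cycles (and at least 4 detected cycles at all).
7. **Labels** (`extract_labels`): ASBP/ADBP are the means of the
   Hampel-corrected ABP peak/valley values of the beats inside the window;
   the SpO2 label is the mean of the SpO2 trace over the window. The
   window-mean choice for SpO2 is a stand-in — how per-slice saturation
   ground truth should be aligned is genuinely underdetermined — and is
   isolated in one function. Slices violating `asbp > adbp` are rejected.

## EMD channelization

Each qualified PPG slice is decomposed by empirical mode decomposition
(`emd_decompose`): iterative sifting with cubic-spline envelopes through the
local extrema, Huang's SD stopping criterion at 0.2 (at most 50 sifting
iterations per mode), extraction stopping when the residue is monotone. End
effects are controlled by mirroring four extrema about each series end
before envelope fitting. The model input (`assemble_channels`) is a 4 x l
matrix: channels 1–3 are IMF1–IMF3 (zero rows where fewer modes exist) and
channel 4 is the input minus the first three channels, so the channel sum
reconstructs the slice *exactly* — the decomposition denoises and separates
scales without losing information. Which EMD outputs form the channels is
not prescribed by the problem; this scheme was chosen because losslessness
is checkable to machine precision.

## The time-series transformer

For a standardized input $X \in \mathbb{R}^{w \times l}$ (each channel
centered and scaled over the non-padded region), the model computes per time
step $z_t = W_p x_t + b_p$, adds learnable positional encodings
$Z' = Z + W_{pos}$, and applies $n$ encoder blocks of multi-head
self-attention,

$$\mathrm{Attention}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right)V,$$

with residual connections, *post*-norm layer normalization after the
attention and feed-forward sublayers, and ReLU feed-forward layers. Scores
at padded key positions are set to $-\infty$ before the softmax, making
predictions provably invariant to padded content (asserted to 1e-5 in the
tests). Scaling by $\sqrt{d_k}$ is the default; a `sqrt_len` switch scales
by the sequence length instead for strict fidelity to the alternative
printed form, which we judged a typographical artifact. The regression path
mean-pools the final representation over non-padded positions and applies a
128-hidden ReLU head with one output per target; the reconstruction path
applies a per-position linear map back to the $w$ channels.

Defaults left open by the problem statement and decided here: `d_model = 128`
with 8 heads and `d_ff = 256` at full scale (consistent with the 128-wide
head and a ~2M parameter budget), dropout 0.1, masking ratio 0.15 with
geometric spans of mean 3 samples, equal loss weights across targets in
multi-task mode.

Everything — forward pass, hand-derived backpropagation, Adam — is
implemented in base R matrix code and verified against central-difference
gradients in the test suite.

### Initialization: a locality bias for masked reconstruction

Masked-span reconstruction requires a masked (zeroed) query position to
attend to its temporal neighbors. With iid-initialized absolute positional
encodings, attention starts uniform over hundreds of keys, gradients into
the scores are scaled by those near-uniform weights, and learning the full
position-adjacency table is prohibitively slow at desk scale. Two
initialization choices (both parameters remain fully learnable) remove this
plateau:

* `W_pos` starts from the classic sinusoidal table, so the inner product of
  two position vectors is a kernel in their distance;
* `W_q`, `W_k` start near `2 * I` (plus small Xavier noise), so initial
  scores are dominated by exactly that kernel — attention is local from the
  first step.

In the package's experiments this initialization moves held-out masked
reconstruction from barely better than predicting the channel mean to
several-fold better than a random-initialized model within a few epochs.

## Training protocol

* **Pre-training** (`tst_pretrain`): unsupervised masked reconstruction
  (MSE over masked positions only) on the training patients' slices; fully
  seeded (shuffling, masks, dropout); best-by-training-loss parameters are
  kept. Batch size 1 is used in the package's own experiments — with
  per-sample backpropagation the number of Adam steps per unit compute is
  what drives convergence here.
* **Splits** (`split_patients`): patient-level 70/10/20 with
  `floor` rounding, patients with fewer than 10 qualified slices (200 s)
  excluded with a logged reason — no patient contributes to two sets.
* **Personalization** (`chronological_split`, `finetune_personalize`): per
  test patient, the chronologically earliest `floor(0.2 n)` slices (at
  least 1) are the fine-tuning portion and the remaining 80% the
  evaluation portion; the chronological tail fifth of the fine-tuning
  portion is held out as the validation set (keeps evaluation untouched and
  preserves time ordering — the validation construction is not prescribed).
  Fine-tuning starts from the pretrained encoder, lr 3e-3 with
  multiplicative decay 0.98/epoch after epoch 50 (the decay coefficient's
  value is a package decision), at most 200 epochs, early stopping after 20
  stagnant validation epochs, best-validation checkpoint returned. Labels
  are standardized internally (statistics from the fine-tuning portion,
  with an SD floor of 1 so single-slice fits stay sane). Adam is the
  optimizer throughout — the standard choice where only a learning rate is
  prescribed.

Leakage guards are structural: evaluation slices never enter any training
batch, and the chronological invariant (last fine-tune slice strictly before
first evaluation slice) is asserted in tests.

## Evaluation and compliance

`compliance_report` aggregates MAE, RMSE, signed mean error, the (n-1)
error SD, squared Pearson correlation (slice-level), Bland–Altman data
(bias ± 1.96 SD limits), the AAMI criterion (pass iff more than 85
subjects, |ME| < 5 mmHg, SD < 8 mmHg — all strict), and BHS grading from
the cumulative percentages of absolute errors within 5/10/15 mmHg (grade A
at 60/85/95, B at 50/75/90, C at 40/65/85; threshold comparisons inclusive,
matching the standard's tabulated `<=` form, with a strictness flag).
AAMI/BHS operate on the pooled per-slice error distribution; per-subject
summaries are available through `subgroup_report`, which flags (never
drops) small groups.

## The synthetic cohort generator

What it emulates: quasi-periodic PPG/ABP beats (asymmetric Gaussian
systolic upstroke plus a smaller dicrotic bump; one unambiguous peak and
valley per cycle), heart rates across the physiological band, per-patient
baseline offsets, additive measurement noise, slow within-record pulse
amplitude modulation (±5%, 60-s period — what makes consecutive slices of
a patient differ), and the three artifact families the QC stage must
catch: flat lines (constant hold), flat peaks (ceiling clipping), and
motion spikes (windowed high-frequency bursts). Ground truth is a *linear*
map — ASBP = 90 + 25·amplitude + 0.25·HR + offset (mmHg), analogous for
ADBP and SpO2, with zero-mean per-beat label noise (SD 2 / 1.5 / 0.3) —
linear precisely so that parameter recovery is analytically checkable. The
ABP waveform is rescaled per beat so its discrete extrema land exactly on
the mapped ASBP/ADBP trajectory. Cohort distributions: HR ~ U(55, 95) bpm,
amplitude ~ U(0.7, 1.3), offset ~ N(0, 10 mmHg), noise SD 0.02.

What it does **not** emulate: real PPG morphology variability (pulse-wave
velocity, reflections, respiration coupling), pathology-specific waveforms,
sensor drift, or any nonlinear pressure–morphology coupling. Passing tests
on this cohort therefore demonstrate that the pipeline's mechanics are
correct and that the model can recover a known morphology-to-pressure map
under personalization — not that clinical accuracy on ICU data is
reproduced.

## Problem sizes and numerical choices

The package's experiments and acceptance checks run on deliberately
desk-scale problems: 30–56 patient cohorts with 220–300 s records (10–14
slices per patient), model inputs decimated by 10 (2,500 → 250 samples;
the PPG band ends at 8 Hz after filtering, so 12.5 Hz sampling loses
little), a 3-layer encoder with `d_model = 32`, 4 heads, `d_ff = 64`, and
single-digit epoch budgets. These sizes are the package's own choices for
reproducible-anywhere experiments; the architecture scales to the full
2,500-sample, `d_model = 128` configuration unchanged.

Numerical guards worth knowing about: standardization passes through
channels with SD below 1e-12 as centered zeros; the anomaly scale has the
2% relative floor discussed above; label standardization floors the SD at
1; layer normalization uses eps 1e-5; the flat-run equality tolerance is
exact by default; all sample indices are 1-based with closed windows (the R
idiom). Seeds: every stochastic entry point takes an explicit seed and
restores the caller's RNG state; child seeds are derived arithmetically and
stay inside the 32-bit range.

## Known limitations

* The transformer trains on CPU at reduced sequence length; full-length
  (2,500-sample) *training* is supported but impractically slow without
  accelerators (full-length inference is fine).
* SpO2 labeling is the window mean of the saturation trace — a stand-in
  where the ground-truth alignment is underdetermined.
* The WFDB reader covers the single-segment, format-16 subset only.
* EMD is the plain sifting algorithm; ensemble variants (EEMD/CEEMDAN) are
  out of scope.
* The AAMI subject-count requirement (>85) cannot pass on desk-scale
  cohorts; the package reports the ME/SD components alongside the verdict.
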