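---
title: "Methods: simulation, segmentation and classification of heart sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation and classification of heart sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pcgdx` implements an end-to-end automated auscultation pipeline —
synthetic phonocardiogram (PCG) generation, denoising, ECG-free S1/S2
segmentation, per-cycle spectrogram features, a small convolutional
classifier, and diagnostic-accuracy statistics. This vignette records the
models, the tunable parameters and their defaults, the numerical choices,
and the design decisions that were genuinely open, so a maintainer can
see *why* the package behaves as it does.

## The synthetic phonocardiogram model

No clinical recordings ship with the package; instead the simulator
produces annotated waveforms whose *timing and band structure* mimic the
five diagnostic classes (normal, S3, S4, systolic murmur, diastolic
murmur).

**Timing.** S1 beats are laid at RR intervals of `60/heart_rate_bpm`
seconds (constant for a regular rhythm). S2 falls at 35% of each RR
interval — the physiologic norm for the systolic fraction at resting
rates. In atrial-fibrillation mode, RR intervals are i.i.d. gamma with
mean `60/HR` and the configured coefficient of variation (default 0.2) —
gamma because it is strictly positive and two-parameter; a refractory
floor of 0.3 s guards the left tail. AF cannot be combined with S4: the
fourth heart sound is produced by atrial contraction, which AF abolishes.

**Timbre.** Heart sound energy concentrates at 20–100 Hz, so:

| component | centre | duration | amplitude (rel. S1) |
|---|---|---|---|
| S1 | 35 Hz | 110 ms | 1.0 |
| S2 | 60 Hz | 90 ms | 0.8 |
| S3 (120–180 ms after S2) | 30 Hz | 60 ms | 0.4 |
| S4 (70–100 ms before S1) | 30 Hz | 60 ms | 0.4 |
| murmur | 40–100 Hz noise | whole systole / 55% of diastole | `murmur_intensity` |

Each transient is a Gaussian-windowed sinusoid (σ = duration/6). The
systolic murmur carries the canonical diamond (crescendo–decrescendo)
envelope between the end of S1 and the start of S2; the diastolic murmur
is a decrescendo starting 60 ms after S2. The waveform is peak-normalized
to 0.9 (headroom against clipping) before environmental noise —
white/pink/mains-hum mixed by power weights — is added at an exactly
realized SNR.

**Annotated times mark the acoustic centre of each sound** (the peak of
its amplitude envelope), not its onset. An envelogram detector localizes
envelope maxima, so centring both the ground truth and the detections on
the same landmark keeps the oracle comparison free of a systematic
half-duration (~55 ms) offset that would otherwise swamp the ±30 ms
matching tolerance.

What the simulator deliberately does **not** model: realistic valve
timbre, respiration and lung sounds, ECG, split S2, murmur radiation, or
device/microphone transfer functions. Tests that pass on this simulator
therefore demonstrate the pipeline's *mechanics* (timing recovery, band
selectivity, learnability of time–frequency patterns), not clinical
performance on real recordings.

## Denoising

The band-pass is a 4th-order Butterworth design, 20–100 Hz, applied
forward-backward (`signal::filtfilt`) — zero phase so S1/S2 timing is
untouched; that attenuates a 500 Hz tone by ~49 dB while holding in-band
gain within 0.1 dB.

Spectral subtraction uses 256 ms Hann frames with 50% hop. The noise
magnitude spectrum is the mean of the lowest-energy 10% of frames (the
quiet diastolic gaps); each frame bin is reduced to
`max(|X| − 1.5·|N̂|, 0.05·|X|)` and the signal is rebuilt by weighted
overlap-add with the original phase. These are conventional
spectral-subtraction settings; frame length, window and floor were open
choices (the method itself fixes none of them). On a clean recording the
operation is close to idempotent (RMS change < 1 dB) because the
self-estimated noise spectrum is then tiny.

The interpretability gate mechanizes the two signal-domain reasons a
bedside phone recording fails review: peak amplitude below `min_peak`
(default 0.01 full scale) flags `LOW_AMPLITUDE`, and an estimated SNR —
envelope-peak power (top decile of a 200 ms power envelope) over
envelope-trough power (bottom quintile) — below `min_snr_db` (default
5 dB) flags `HIGH_NOISE`. The envelope window is deliberately long:
at shorter windows the sampling spread of a stationary noise envelope
alone produces several dB of apparent peak/trough contrast. For the same
reason the pipeline gates on the *band-passed* signal, before spectral
subtraction — denoising reshapes the noise statistics and can make pure
noise look pulsatile. A third real-world failure cause, poor patient
cooperation, has no signal-domain analogue and is not modeled. The gate
is advisory: `run_pipeline()` excludes flagged recordings from the metric
denominators (mirroring an analysis restricted to interpretable sounds)
unless `include_uninterpretable` is set.

## Segmentation

The envelogram is the normalized average Shannon energy: per sample
`−x² ln x²` (with `0·ln 0 := 0`) on peak-normalized input, averaged over
20 ms windows, standardized to zero mean/unit variance. Shannon energy
accentuates mid-amplitude transients — its per-sample maximum `e⁻¹` is
attained at `|x| = e^(−1/2)` — which suppresses both the noise floor and
occasional sharp spikes. Analysis runs at a 1 kHz working rate
(anti-aliased); the default hop is 5 ms rather than the 10 ms typical of
classic envelograms, and peak times are refined by three-point quadratic
interpolation, so event timing resolution is comfortably inside the
±30 ms tolerance used to score the detector.

Candidate events are local maxima above +0.5 standard units separated by
at least 120 ms (shorter than any physiologic systole; the taller peak
wins a conflict), with a half-threshold re-scan of inter-event gaps
longer than 1.5× the median (`recovery`).

Labelling the candidates as S1/S2 was the most genuinely open design
area, because extra envelope humps (S3, S4, murmur crescendos) must not
corrupt the cycle structure:

1. the RR interval is estimated from the envelope autocorrelation over
   physiologic lags (0.3–2 s), comb-scored (`ac(L) + 0.5·ac(2L)`) so
   sub-harmonic spacings such as the diastolic interval are not picked;
2. a dynamic program selects the strongest near-periodic chain of events
   at that period (off-period steps are quadratically penalized; a step
   of ~two periods — one missed beat — costs a modest flat penalty);
3. two hypotheses about the chain compete: it is the S1 train, or it is
   the S2 train (in which case S1 is the event a systolic interval
   before each chain beat). Each hypothesis is completed into a full
   labelling — the train is extended outward beat by beat, residual
   errors under irregular rhythm are corrected against a per-recording
   height model (the two sound trains have distinct typical Shannon
   heights), and S2 is located in each cycle's systolic window with a
   timing prior centred at 35% of RR;
4. labellings are scored by physiologic plausibility: the number of
   valid cycles (S1 < S2 < next S1, systole shorter than diastole),
   damped by how far the median systolic fraction sits from 35% and by
   its spread — a true labelling puts S2 at a near-constant fraction of
   every cycle, even in AF. This scoring subsumes the classic
   "systole is the shorter interval" rule and stays robust when a loud
   murmur's envelope hump forms a periodic train of its own;
5. because the period estimate can lock onto a harmonic, the halved,
   doubled, 2/3 and 3/2 periods also compete under the same score.

Recordings that yield fewer than four events, or no periodic train,
raise a *typed* segmentation failure rather than crashing — the pipeline
records the recording as unsegmentable and moves on.

## Features

Each cycle (S1 onset to next S1) is peak-normalized — making the feature
exactly gain-invariant, which matters when several phone models with
different gains record the same patient — linearly time-warped to a
canonical 800 ms, and analyzed with a 64 ms Hann STFT (75% overlap,
256-point FFT) at 1 kHz. Magnitudes are compressed as `log(1+|X|)`,
cropped to 10–200 Hz (the heart-sound band with margin), bilinearly
resized to exactly 40×40 (rows = time, columns = frequency) and min–max
normalized to `[0, 1]`; an all-zero cycle maps to the all-zero matrix.
Whether the upstream design computed one matrix per cycle or per fixed
window is unknowable from its description; per-cycle is used here since
cycle boundaries are what segmentation provides, and it gives the
classifier a rate-invariant, aligned input.

## Classifier

The network is fixed by its published architectural facts — 40×40 input,
two convolution/max-pool blocks with 5×5 kernels and 8 then 16 kernels, a
dense layer, a 5-node readout, softmax cross-entropy, Adam at learning
rate 0.001 — and completed with the standard choices where it was silent:
ReLU activations, 2×2/stride-2 pooling, valid (no-padding) convolutions,
a 128-unit dense layer, batch size 32, and up to 30 epochs. Training
stops early once training accuracy has held at 100% for three consecutive
epochs; on the cleanly separable synthetic classes this typically
triggers near epoch 10–15 and the loss surface is flat for classification
purposes thereafter. No deep-learning framework is used: convolutions run
as im2col patch gathers followed by BLAS matrix products, max-pooling and
its argmax routing as precomputed index gathers, and the Adam update and
backward pass are written out explicitly; gradients were verified against
finite differences. Everything is seeded (initialization and the
per-epoch shuffle), so two runs with the same seed produce bit-identical
parameters and predictions.

A recording's diagnosis aggregates its per-cycle probability vectors by
the arithmetic mean — the simplest order-invariant rule — and, when the
truth is known, counts as correct iff the true class receives at least
50% of the aggregated probability (exactly 0.5 counts).

Class balance is handled by generating balanced training data rather
than by loss weighting, since the simulator is under our control. For
the end-to-end property bar the training set is 400 recordings (80 per
class, heart rates 50–110 bpm, murmur intensities 0.3–0.8, SNR
15–30 dB), capped at 6 cycles per recording so slow and fast hearts
contribute equally; evaluation uses 100 independent recordings (20 per
class) with all their cycles. These sizes keep a full train/evaluate
cycle at a few minutes on one CPU while leaving the bar (≥ 85%
recording-level accuracy under the 50% rule) a real test of the whole
chain — segmentation errors, feature misalignment or optimizer defects
all show up as misclassified recordings.

## Evaluation statistics

Predictions and truths are dichotomized (normal = negative; S3, S4 and
both murmurs = positive — inferred from the single
sensitivity/specificity reported per device in the study design this
mirrors), confusion counts accumulated, and the five standard
proportions computed exactly: accuracy `(TP+TN)/n`, sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV
`TN/(TN+FN)`. A metric with a zero denominator is reported as undefined
(`—`), never as 0 or 100%.

Confidence intervals are exact Clopper–Pearson, in the Beta-quantile
form `lower = qbeta(α/2, k, n−k+1)`, `upper = qbeta(1−α/2, k+1, n−k)`,
with the conventional boundary conventions (`k=0 ⇒ lower=0`,
`k=n ⇒ upper=1`). The exact method was chosen because it reproduces the
published intervals of the reference table for every non-boundary cell
at the reconstructed counts; the test suite also verifies the
Beta-quantile form against brute-force bisection of the binomial CDF to
10⁻⁶ for all `k ≤ n ≤ 50`. For the two boundary (100%) cells, the
published intervals are inconsistent with Clopper–Pearson at any
plausible denominator, so no agreement is asserted there — the published
boundary-case method is unknown.

## Numerical and degenerate-input choices

* `0·ln 0 := 0` in the Shannon transform; an all-zero signal yields an
  all-zero (unstandardized) envelope, and a zero-variance envelope
  standardizes to zeros rather than NaNs.
* Spectral subtraction pads to whole frames and normalizes overlap-add
  by the summed squared window (guarded at 10⁻⁸); output is trimmed to
  the input length and clipped to [−1, 1].
* Min–max normalization of a zero-range spectrogram returns the all-zero
  matrix.
* Softmax is computed with the max-subtraction trick; training clamps
  probabilities at 10⁻¹² inside the log.
* The last detected cycle's end is extrapolated by the median RR and
  clipped to the recording end before feature extraction.
* All user-facing validation failures are typed conditions
  (`pcgdx_config_error`, `pcgdx_data_error` and subclasses), naming the
  offending field.

## Known limitations

* The simulator's spectra are far cleaner than real phone recordings;
  the reported property bars do not transfer to clinical data.
* The interpretability gate is a two-threshold heuristic standing in for
  human adjudication.
* Segmentation assumes a dominant periodicity; rhythms beyond AF-like
  RR jitter (bigeminy, frequent ectopy) were not designed for.
* The classifier is intentionally small and is trained per run; no
  pretrained weights ship with the package.
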