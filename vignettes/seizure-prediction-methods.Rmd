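---
title: "Seizure prediction from gamma-band scalp EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure prediction from gamma-band scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preictal)
```

## The problem

Epileptic seizures are preceded, in many patients, by a *preictal* period in
which the statistical structure of the scalp EEG changes before any clinical
sign. A seizure predictor is a classifier that watches the ongoing
multichannel EEG and raises an alarm when the current activity looks
preictal rather than *interictal* (the between-seizure baseline). `preictal`
implements an end-to-end version of this idea: no hand-crafted features, a
single frequency band of the raw signal fed to a recurrent network, and an
evaluation layer that scores alarms the way a clinical trial would.

The pipeline is patient-specific. For each subject it:

1. reads continuous EDF recordings and plain-text seizure annotations onto
   one monotonic timeline (gaps between files are kept, never elided);
2. labels every recorded second as preictal, ictal, postictal, interictal
   or excluded buffer;
3. band-pass filters the continuous signal (gamma, 30–128 Hz, by default),
   cuts it into non-overlapping 5-s windows, and screens windows for
   EMG artifacts;
4. trains an LSTM on the first seizures' windows and predicts the rest;
5. fuses per-window predictions into segment decisions by majority vote,
   and into alarms scored under the SOP/SPH framework with a
   random-predictor significance test.

## Stage labeling

A seizure is **leading** — a prediction target — when its onset lies more
than 60 min after the previous seizure's end; clustered seizures are not
separately predictable. The **preictal** period is the hour before a
leading seizure; **postictal** is the hour after any seizure's end;
**interictal** time must lie at least 5 h after the previous seizure and
3 h before the next, so that slow pre- and post-seizure drifts cannot
contaminate the baseline class. Everything recorded that fits none of
these definitions is an excluded buffer.

Two conventions are ours, because the underlying definitions do not fix
them:

* **Precedence.** Where zones overlap (seizures closer than two hours),
  one stage must win. We use ICTAL > PREICTAL > POSTICTAL > EXCLUDED >
  INTERICTAL: preictal data for a predictable seizure is never sacrificed
  to the previous seizure's postictal window, while interictal purity is
  absolute (interictal loses to everything).
* **First seizure.** A subject's first seizure is leading only if its full
  preictal hour was actually recorded; a predictor cannot be trained or
  scored on time that was never measured.

All times are half-open intervals `[start, end)` in seconds on a
per-subject timeline; `assign_stages()` tiles the recorded time exactly
(property-tested against a brute-force per-second labeler).

## Filtering and windowing

The five standard EEG bands are delta (0–4 Hz), theta (4–8), alpha (8–13),
beta (13–30) and gamma (30–128). At the 256 Hz sampling rate of the target
recordings the nominal gamma upper edge sits at the Nyquist frequency, so
the realizable passband is 30–127.5 Hz. Filters are Hamming windowed-sinc
FIRs with ≈2 Hz transition bands (order ≈ `3.3·fs/2` ≈ 422 at 256 Hz),
applied to the *continuous* record — not to 5-s windows, which would incur
edge artifacts in every window — with exact group-delay compensation, so
the output is zero-phase. We deliberately use a single centered
convolution pass rather than a forward–backward pass: a symmetric kernel
applied this way already has exactly zero phase, the designed stopband
attenuation (not its square) is what the contract tests assert, and there
is only one edge transient per record end. Channels are mean-centered
before filtering; for the delta band this makes the output "0–4 Hz minus
DC".

Windows are 5 s, non-overlapping, anchored at each stage interval's start;
windows straddling a stage boundary or a file edge are dropped. A window
becomes a classifier sample only for the preictal/postictal/interictal
stages.

**EMG screening.** Muscle artifacts are broadband with most power above
60 Hz and often large. The original screening of such windows was manual;
for reproducibility we use a deterministic two-rule policy: reject a
window if any channel exceeds 500 µV peak, or if on any channel more than
85% of the non-DC power lies above 60 Hz. Both thresholds are exposed
(`amp_max_uv`, `hf_frac`). On gamma-filtered 1/f background the >60 Hz
fraction is ≈0.5, far from the threshold, so clean data are untouched.

**Class balance.** Interictal hours dwarf the preictal ones, so the
interictal training samples are uniformly undersampled (seeded, without
replacement) to the largest non-interictal class size. Test data are never
balanced.

## The classifier

The network is intentionally minimal: input of `1280 × 23` (5 s × 256 Hz
time steps, 23 channels), one LSTM layer with 128 memory units, dropout
0.5 on its final hidden state, a fully connected layer whose width equals
the number of classes (2, or 3 when postictal is modeled as its own
class), and a softmax. The sequence axis is time; channels are the
per-step features.

Training details the architecture does not fix are set as follows and
exposed in `model_config()`: Adam with learning rate `1e-3`, batch 64, at
most 30 epochs, early stopping (patience 5) on a seeded 10% validation
split, categorical cross-entropy, global-norm gradient clipping at 5,
Glorot-uniform initialization with forget-gate bias 1, and per-channel
z-scoring whose statistics come from the training split only. The
implementation (forward pass, backpropagation through time, Adam) is in
RcppArmadillo and is bit-reproducible given the seed.

Two data splits are provided and never mixed in one run: the
chronological *first-k-seizures* split (train on the first two seizures'
data plus earlier interictal; predict the rest — the deployment
scenario), and *leave-one-seizure-out* (average over rounds, for
subjects with few seizures). The first-k split also offers a
`train_on = "postictal+interictal"` recipe that uses the first seizures'
postictal hours as the positive training class: post- and pre-seizure
EEG share gamma-band structure, while seizures can shift the interictal
baseline itself, so a postictal-trained baseline can be the more robust
stand-in for later preictal detection. Sample-level 10-fold cross-validation is
also available for segment-based evaluation. Normalization and balancing
are recomputed inside every training split; leakage is property-tested.

### The reduced profile

`reduced_model_config()` is a first-class preset for CPU-scale work: 32
memory units, at most 10 epochs, and temporal stride 8 (160 steps per
window). The quantity the classifier exploits — within-window band
power — is invariant under decimation of a stationary signal, so the
stride changes compute, not the learning problem. The full-size profile
is the default for real data.

## Evaluation

**Segment fusion.** Per-sample predictions are fused over segments of
`L` seconds: in the 2-class task a segment is preictal iff *strictly*
more than half of its samples are; in the 3-class task iff strictly more
than one third are (otherwise the plurality of the remaining classes,
ties to interictal). All thresholds are compared in integer arithmetic.
`mtpw_scan()` sweeps `L` from 5 to 150 s and reports the curve plus the
minimum time prediction window (MTPW), the smallest `L` whose
sensitivity and specificity are within tolerance of their later maxima.
Under an i.i.d. per-sample accuracy model the fused sensitivity has a
binomial closed form, which the tests check at `L = 120 s`. One subtlety
of the strict threshold: the exact binomial curve is *not* globally
non-decreasing in `L` — even sample counts need one vote more than half,
so the curve zigzags between parities (0.80 at one sample versus 0.64 at
two, at accuracy 0.8) while rising within each parity class; the tests
assert the parity-stratified monotonicity.

**Alarms.** An alarm is raised when strictly more than 70% of the
trailing 10 min of samples (120 windows) are predicted preictal. The
window slides one sample at a time (a tumbling mode exists behind a
flag), resets at recording gaps, and after an alarm stays silent for a
refractory period of SPH + SOP = 50 min, so one alarm covers one
prediction window.

**SOP/SPH scoring.** An alarm at time `t` is correct iff a leading
seizure starts within `[t + SPH, t + SPH + SOP)` with SPH = 30 min (the
intervention horizon, which must stay seizure-free) and SOP = 20 min
(the period in which the seizure must occur). Sensitivity is the
fraction of leading seizures with at least one correct alarm; the false
prediction rate (FPR) is false alarms per hour of evaluated non-ictal
test recording (interictal only in the 2-class task; interictal +
postictal in the 3-class task); the warning time is onset minus first
correct alarm, necessarily in `[SPH, SPH + SOP)`. Significance against
an unskilled predictor uses `P = 1 − exp(−FPR·SOP)` and the binomial
tail `p = Σ_{i≥m} C(M,i) P^i (1−P)^{M−i}`, with significance declared
at `p < 0.05`.

One property of this strict framework is worth stating because the
synthetic tests expose it: a classifier that detects the preictal state
*immediately* produces its first alarm exactly 10 min into the preictal
hour, i.e. exactly SPH + SOP before onset — one boundary instant too
early to be correct. Real preictal transitions are gradual and real
classifiers imperfect, which is precisely why reported warning times sit
just below the 50-min ceiling rather than on it. On step-change
synthetic data with a near-perfect classifier, event-level sensitivity
is therefore legitimately low even when segment-level metrics are
perfect; the event layer's correctness is established by its own
pairing-oracle tests, and event-level *calibration* is checked on null
data, where the chance model applies.

**Postictal drift.** `postictal_drift_profile()` bins binary-task
predictions by time since the preceding seizure's end and reports the
fraction classified preictal per hour — the diagnostic that motivates
adding postictal as a third class.

## The synthetic generator

No clinical data ship with the package; `generate_recording()` /
`generate_subject()` create the study conditions instead. The signal
model is multichannel `1/f^α` Gaussian background (α = 1, RMS 30 µV,
low-frequency knee at 0.5 Hz) whose per-band power is multiplied by
stage-dependent gains — by default preictal gamma ×1.5 and postictal
gamma ×1.25 against interictal baseline, the premise that gamma-band
structure distinguishes the stages. Ictal spans add a 4 Hz rhythmic
burst (300 µV with a harmonic); optional EMG-like artifacts are >60 Hz
bursts of 200–2000 µV, 0.5–2 s, on up to three channels at a Poisson
rate. Spans are synthesized independently in the frequency domain, so a
configured gamma multiplier is realized *exactly* in expectation
(verified within 10% on ≥10-min spans). Channels are independent;
spectra are smooth.

`generate_subject()` lays out a realistic multi-record subject: one
record around each seizure covering the full preictal hour plus a
postictal stub, and interictal records centered inside the buffered
zones of each gap (9 h offset-to-onset by default, whose buffered zone
is exactly one hour), plus leading/trailing interictal records. Records
are written as 16-bit EDF plus a CHB-MIT-style summary file, and the
staging of the re-read files recovers the ground truth exactly — the
round trip is itself a test.

What the generator does *not* emulate: spatial correlation between
channels, non-stationary background, physiological seizure morphology,
gradual preictal onset, or patient-to-patient variability. Passing
tests therefore demonstrate that the pipeline recovers controlled
band-power structure end to end and that its statistics are calibrated
under the null — not that the classifier will reach any particular
performance on clinical recordings.

## Problem sizes and numerical choices

The test battery runs two kinds of end-to-end problems, chosen as the
smallest sizes that still exercise every stage at the default staging
policy: a signal subject (4 seizures, 9-h gaps, preictal gamma ×2,
≈9.8 h recorded) whose fused 120-s sensitivity and specificity must
reach 0.85, and five null subjects (3 seizures each, no contrast) whose
fused metrics must average within 0.5 ± 0.15 and whose event-level
predicted fraction must sit inside the central 95% of the
random-predictor binomial. Unit tests use a further-scaled staging
policy (minutes instead of hours) for wiring-level checks; the
synthetic-data module accepts any policy, so these are the same code
paths.

Numerical conventions worth knowing: half-open interval arithmetic
everywhere with exact breakpoint construction (no per-second
rasterization in the implementation — only the test oracle rasterizes);
integer-exact majority thresholds; alarms stamped at the end of the
window that completes them; EDF quantization of ±5000 µV into 16 bits
(step ≈ 0.15 µV, ~340× below the background RMS); and every random
choice (initialization, shuffling, dropout, validation split,
balancing, synthesis) derived from explicit seeds, so whole runs are
reproducible from their manifest.

## Limitations

The package is a research instrument for the stated method, not a
clinical device. Known limitations: patient-specific training only (no
cross-subject transfer); the EMG screen is a two-rule heuristic, not an
artifact-correction method; non-256 Hz recordings are accepted but the
model input length then follows `fs`; p-values from few seizures are
coarse by nature; and the strict SOP/SPH boundary behavior on
step-change data discussed above.
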