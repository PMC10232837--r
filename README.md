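# preictal

End-to-end epileptic seizure prediction from multichannel scalp EEG in R.

Many epilepsy patients have a measurable *preictal* state: minutes to an
hour before a seizure, the spectral structure of the EEG drifts away from
the interictal baseline. `preictal` implements a complete patient-specific
prediction pipeline around that observation, for researchers working with
long-term scalp EEG (CHB-MIT-style recordings: 23 bipolar channels,
256 Hz, EDF files plus plain-text seizure annotations):

* **io** — minimal 16-bit EDF reader/writer and a parser for
  CHB-MIT-style seizure summary files, mapping multi-file subjects onto
  one monotonic timeline.
* **staging** — turns seizure annotations into a four-stage labeling:
  preictal = 1 h before each *leading* seizure (one separated from the
  previous seizure by > 60 min), ictal, postictal = 1 h after offset,
  interictal = ≥ 5 h after / ≥ 3 h before any seizure; the rest is
  excluded buffer.
* **preprocessing** — zero-phase FIR filtering into the five standard EEG
  bands (δ 0–4, θ 4–8, α 8–13, β 13–30, γ 30–128 Hz), non-overlapping 5-s
  windows, deterministic EMG-artifact screening, interictal
  undersampling.
* **model** — an LSTM sequence classifier (1280 × 23 input, 128 memory
  units, dropout 0.5, softmax; implemented from scratch in
  RcppArmadillo with Adam, BPTT and early stopping), with
  first-k-seizures, leave-one-seizure-out and stratified k-fold splits.
* **evaluation** — majority-vote segment fusion (preictal iff strictly
  more than 1/2 — or 1/3 in the 3-class task — of samples are preictal),
  the minimum-time-prediction-window scan, the 70%-in-10-min alarm rule,
  and event scoring under SOP/SPH: an alarm at `t` is correct iff a
  leading seizure starts in `[t + SPH, t + SPH + SOP)` (SPH 30 min,
  SOP 20 min), with false prediction rate per hour, warning times, and a
  random-predictor test `P = 1 − exp(−FPR·SOP)`,
  `p = Σ_{i≥m} C(M,i) P^i (1−P)^{M−i}`.
* **synthetic** — a generator of EEG-like subjects (1/f background with
  stage-dependent band-power multipliers, rhythmic ictal bursts, optional
  EMG artifacts) written out as EDF + summary files, so the entire
  pipeline is testable without clinical data.
* **pipeline** — one-config orchestration (`run_config()` /
  `run_pipeline()` / `compare_bands()`), YAML config support and a thin
  CLI at `inst/cli/preictal`.

## Worked example

A scaled-down synthetic subject (stage durations in minutes rather than
hours, 3 channels) keeps the example fast; the code path is identical to
the full-scale setting.

```r
library(preictal)

pol <- staging_policy(leading_gap_s = 600, preictal_len_s = 600,
                      postictal_len_s = 600,
                      interictal_pre_buffer_s = 3000,
                      interictal_post_buffer_s = 1800)
cfg <- synth_config(n_channels = 3, band_power = list(PREICTAL = c(gamma = 3)),
                    seed = 42)
sub <- generate_subject(cfg, n_seizures = 4, gap_s = 5400, dir = tempfile(),
                        policy = pol, ictal_len_s = 30,
                        postictal_record_s = 630, interictal_record_s = 600,
                        lead_in_s = 30)
rc <- run_config(task = 2, staging = pol,
                 model = reduced_model_config(n_channels = 3, seed = 42),
                 segment_len_s = 120, mtpw_lengths = c(5, 30, 60, 120),
                 alarm_window_min = 5, sop_s = 300, sph_s = 300,
                 refractory_s = 600, seed = 42)
res <- run_pipeline(sub, rc)
print(res)
#> Pipeline result (2-class, band gamma)
#>   segment (120s): sensitivity 1.0000, specificity 1.0000 (n=20)
#> <event_eval: 2/2 seizures predicted (100.0%), FPR 0.000/h, p=0>
res$mtpw$curve
#>   length_s sensitivity specificity n_segments
#> 1        5   0.9958333           1        480
#> 2       30   1.0000000           1         80
#> 3       60   1.0000000           1         40
#> 4      120   1.0000000           1         20
```

Reading: the subject's last two seizures (the first two train the model)
are evaluated. At the 5-s sample level the classifier is right 99.6% of
the time on preictal windows and always on interictal ones; fusing 120-s
segments makes both metrics 1.0. Both held-out seizures are predicted
with 300-s warning times (the earliest the 5-min alarm window allows
here), with no false alarms, so the random-predictor p-value is ≈ 0.

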