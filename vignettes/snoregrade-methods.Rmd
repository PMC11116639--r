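---
title: "Methods: grading sleep apnea severity from snoring audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grading sleep apnea severity from snoring audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoregrade)
```

## The problem and the model

Obstructive sleep apnea–hypopnea syndrome (OSAHS) is characterized by
repeated interruptions of breathing during sleep. Its clinical severity
measure is the apnea–hypopnea index, AHI = N/t: the number of respiratory
events N per hour of sleep t, binned into four grades — normal/simple
snoring (AHI < 5), mild (5 ≤ AHI < 15), moderate (15 ≤ AHI < 30), severe
(AHI ≥ 30). `snoregrade` estimates a night's grade from audio alone, by
detecting apnea on a per-minute basis and counting.

The detection model is deliberately simple and auditable:

* Each minute of audio is summarized by a 13-dimensional MFCC vector —
  the log-mel spectrum decorrelated by a cosine transform — which captures
  the spectral envelope of snoring versus its absence.
* The per-minute MFCC vector is additionally rendered as a sentence-like
  string and passed through a sentence encoder, giving a second,
  "semantic" view of the same minute. The two views are concatenated.
* A gradient boosted tree classifier maps the fused vector to a
  probability that the minute contains an apnea event; minutes with
  score ≥ 0.5 are counted as events; AHI and the grade follow.

The assumptions are that apnea manifests acoustically as a change in the
minute's spectral envelope (chiefly the suppression of snoring), that
minutes are exchangeable given their features (no temporal model), and
that per-minute positives are an acceptable proxy for clinical event
counts (see *Event counting* below).

## Labeling: the 30-second rule

Ground-truth annotations are intervals `[start_s, end_s)` in seconds.
A minute t (the half-open window `[60(t−1), 60t)`, t = 1…T,
T = ceil(duration/60)) is labeled positive under the default
`event_duration` rule when some apnea event of total duration ≥ 30 s
overlaps it. The rule's phrasing admits a second reading, implemented as
`within_minute_overlap`: at least 30 s of apnea *inside* the minute. The
duration reading is the default because the criterion is stated about the
event's duration, and because the overlap reading silently drops 30–59 s
events that straddle a minute boundary. The threshold is inclusive
(exactly 30.000 s counts). Both rules are verified against a per-second
brute-force oracle in the test suite.

A consequence of the duration rule worth knowing: a long event marks every
minute it touches, so a minute can be "apnea-positive" while containing
only a few seconds of actual apnea. Those minutes are genuinely hard for
any per-minute acoustic classifier and dominate its errors.

## Tunable parameters

All knobs live in `run_config()`; every run can persist its resolved
configuration as YAML.

| group | parameter (unit) | default | rationale |
|---|---|---|---|
| framing | `frame_length_s` (s) | 0.025 | standard speech analysis frame |
| framing | `hop_length_s` (s) | 0.010 | standard 60% overlap |
| framing | `window_name` | hamming | standard sidelobe suppression |
| spectrum | `n_fft` | auto | smallest power of two ≥ frame length |
| mel | `n_mel_filters` | 26 | common M for 13 cepstra |
| mel | `n_mfcc` | 13 | static coefficient count used throughout |
| mel | `fmin_hz`/`fmax_hz` (Hz) | 0 / Nyquist | full band; snoring is low-frequency |
| log | `log_floor` | 1e-10 | guards log(0) on silent filters |
| aggregation | `minute_aggregation` | mean | see below |
| encoder | `encoder_dim` | 8 | compact; information check in tests |
| encoder | `encoder_precision` | 4 decimals | round-trip parseable sentences |
| boosting | `learning_rate` … `gamma` | 0.3, 9, 0.6, 10, 0.1, 0.5, 0.2 | tuned classifier settings |
| boosting | `n_rounds` | 100 | not part of the tuned set; conventional |
| decision | `decision_threshold` | 0.5 | scores are calibrated probabilities |
| grading | `severity_thresholds` (AHI) | 5, 15, 30 | clinical bins |
| split | `train_fraction` | 0.8 | night-level 80/20 split |

Design points that were genuinely open, and the choices made:

* **Mel mapping.** The standard HTK form m = 2595·log10(1 + f/700) — the
  most widely used convention, so results are comparable with common
  tooling. The natural logarithm is used for filter energies.
* **Cepstral indexing.** Coefficients are C_l for l = 1…13 from the
  unscaled DCT-II sum; there is no C₀ energy term. Dynamic (delta)
  coefficients are not computed — nothing downstream consumes them.
* **Minute aggregation.** Frame-level cepstra are averaged per minute
  (a frame belongs to the minute its start falls in). Median and
  mean±sd aggregation are available by configuration; the mean is the
  default as the least surprising choice. Minutes with no frames are
  zero-filled and flagged.
* **Standardization scope.** The per-column z-scaler (population SD) is
  fitted on training nights only and applied to held-out nights, so the
  80/20 split leaks nothing; constant columns get a unit divisor.
* **Sentence format.** `"[v1, v2, …, v13]"` at 4 decimals — defined by
  this package, config-exposed, and exactly round-trip parseable, which
  the fallback encoder relies on.
* **Fallback encoder.** A seeded random projection (entries N(0,1),
  scaled by 1/√13) of the parsed coefficients followed by tanh. It is
  deterministic, download-free, and preserves enough information that a
  classifier on semantic features alone beats chance on synthetic nights
  (tested). A pretrained biomedical language model can be plugged in via
  `encoder_backend()`, with first-token or mean pooling; absent weights
  the package fails loudly rather than silently substituting.
* **Label leakage.** A literal reading of per-minute fusion would include
  the event label e_t itself among the features of minute t. Since e_t is
  the prediction target, the default `inference_safe` mode excludes it; a
  `paper_faithful` mode reproduces the literal concatenation, warns, and
  is covered by a test demonstrating the circularity (training accuracy
  ≈ 1 on pure noise features).
* **Event counting.** `positive_minutes` (default) counts each predicted
  apnea minute as one event — the convention consistent with a per-minute
  classifier whose counts divide to reference AHI values like 389/8 =
  48.625. `contiguous_runs` (maximal runs of positive minutes) is the
  clinically conventional alternative and is one switch away.
* **Division-by-zero sentinels.** Precision/recall/specificity return 0
  with a warning when undefined; R² returns 0 with a warning when the
  target has zero variance. Reports never contain NaN.
* **R² variant.** The standard R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² is the default;
  a `paper_faithful_r2` flag computes the denominator as Σ(ȳ−ŷ)² for
  comparability with sources using that variant.

## The synthetic-data generator

`simulate_night()` emulates the one acoustic contrast the pipeline needs:
snoring present versus snoring suppressed.

* Baseline audio is breath-synchronous snore bursts — a five-harmonic
  stack at a per-night fundamental drawn from 80–150 Hz,
  amplitude-modulated by a squared-sine inspiration envelope with a 4-s
  breath period — over white background noise (SD 0.01, snore gain 0.25).
* Apnea events silence the snoring while the noise floor remains. Events
  are placed uniformly at random without overlap (≥ 5 s gaps), count =
  round(target_AHI × hours), durations uniform in 20–90 s so that both
  sub-30 s (unlabeled) and ≥ 30 s (labeled) events occur and the
  30-second rule is genuinely exercised.
* Annotations are written exactly at the silenced intervals and the truth
  record is `label_minutes()` of those annotations, so generator and
  labeler close the loop by construction (tested over 100 random specs).
* `simulate_cohort()` draws per-night severity classes in given
  proportions and target AHIs uniform within class bands (0–5, 5–15,
  15–30, 30–45/h). Severe is capped at 45/h because an 8-h night cannot
  physically hold many more 20–90 s events with gaps; the realized event
  count is snapped inside the class band so each night's realized AHI
  grades back to its intended class. Per-night seeds derive from the
  master seed; everything is bit-reproducible.

What the generator does **not** emulate: real snore timbre and its
within-night drift, body-position and stage effects, hypopneas with
partial rather than absent snoring, gasps at event termination, room
noise that correlates with events, and inter-patient variability beyond
the fundamental frequency. Passing the end-to-end tests therefore shows
the pipeline's machinery is sound and its features separate the
constructed contrast — it does not certify clinical performance.

## Problem sizes and evaluation design

Unit and property tests run a reduced profile — 20-minute nights at
4 kHz with 15–40 s events (`short_night_spec()`) — chosen so the full
audio path runs in seconds while every stage still operates on thousands
of frames per minute. Full 8-h/8-kHz nights use identical code paths.

The headline recovery check simulates a balanced 12-night cohort, trains
on 80% of nights, and grades held-out nights. An 80/20 split of 12 nights
holds out only 2, too few to estimate a rank correlation between realized
and estimated AHI — a single all-negative night makes it undefined. The
evaluation therefore rotates six disjoint 2-night held-out folds (each
fold's model still trains on 10 nights) and pools the out-of-sample
gradings, so all 12 nights are graded held-out exactly once. Exact-match
accuracy is compared against the 25% four-class chance level, and the
pooled Spearman correlation must be positive. Truth labels for this
comparison are derived from the generator's ground-truth minute records
through the same count → AHI → grade path as the predictions, so both
arms are graded identically.

## Numerical notes

* The FFT path (`stats::fft`/`mvfft`) is verified against a naive O(N²)
  DFT oracle at 1e−9 relative error, and the cepstral transform against a
  double-loop evaluation of its defining sum at 1e−10.
* `n_fft` must be a power of two (fast-transform requirement); frames are
  zero-padded up to it.
* ROC/AUC uses a threshold sweep with tie groups and trapezoidal
  integration, which equals the all-pairs rank statistic with ties
  counted half (tested exactly, and against an independent
  implementation).
* Boosted-tree training is single-threaded and seeded; identical data,
  configuration and seed reproduce identical predictions bit-for-bit.

## Known limitations

* Per-minute positives conflate event count with event duration: one
  3-minute apnea contributes three "events". The `contiguous_runs`
  counter mitigates this but changes the AHI scale; neither is a
  clinically validated event counter.
* Minutes brushed by a long event for a few seconds are labeled positive
  but look acoustically normal; recall on such minutes is structurally
  poor, which biases predicted AHI downward on sparse nights.
* Sleep time t is taken as recording duration — there is no sleep staging,
  so wake time inflates the denominator relative to true AHI.
* The pretrained-encoder path is an interface; all shipped results use
  the deterministic fallback encoder.
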