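---
title: "Baseline-adjusted pain visualization from ICU vital signs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline-adjusted pain visualization from ICU vital signs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many critically ill patients cannot self-report pain, and behavioral scales
such as the Critical-Care Pain Observation Tool (CPOT, 0-8) are charted only
intermittently — typically every 8 h. Vital signs, by contrast, are recorded
every minute. `painindex` implements a pipeline that learns, from intermittent
CPOT assessments, a continuous **pain index**: the predicted probability that
a concurrent CPOT score would be 3 or higher, displayed as 0-100%. Its
distinguishing feature is that vital signs enter the model as *deviations
from a per-patient baseline*, not as raw values, so that between-patient
differences in resting physiology (vascular, cardiac, autonomic) do not
masquerade as pain.

The pipeline has six stages: synthetic-cohort generation (for validation),
plausibility filtering, baseline establishment, feature extraction,
class-balanced random-forest training, and evaluation (discrimination plus
analgesic treatment response).

## Baseline establishment

A patient's baseline cannot be read off at admission: the first hours in the
ICU are physiologically unstable. The baseline module scans candidate 1-h
windows `[s, s + 60)` starting at admission and advancing by 20 min after any
failure, and accepts the first window in which **every** model vital (HR,
SBP, MBP, DBP, RR) passes three gates:

1. **Coverage** — at least 90% of the 60 minutes present. Interior gaps are
   then linearly interpolated between the nearest present neighbors and edge
   gaps filled by nearest-value extension (two-tailed linear completion).
2. **Friedman rank test** — the hour is split into three chronological
   20-min segments; the Friedman test (segments as treatments, within-segment
   minute position as blocks) must *not* reject at `alpha = 0.05`. This
   catches monotone drift that a variance test misses. The blocking by minute
   position is the only blocking structure available within a single hour of
   a single patient.
3. **Coefficient of variation** — sample SD / mean must not exceed a
   per-vital threshold (HR/SBP/MBP/DBP 0.10, RR 0.20, SpO2 0.02), boundary
   inclusive. Published per-vital thresholds exist but are not enumerated in
   an accessible form, so these conservative stand-ins are defaults and fully
   configurable.

The per-vital baseline is the mean of the final 5 minutes of the accepted
(interpolated) window — the window-final 5-min moving-average value — and is
treated as a constant reference thereafter. An alternative reading would keep
the whole 5-min moving-average *curve* as the reference; we chose the scalar
anchor because it makes "area above/below the baseline" well defined at any
later time without extrapolating a curve. SpO2 is excluded from the gates by
default because it is not an explanatory variable of the model. No baseline —
and therefore no pain index — exists before the accepted window ends, which
is why the pain index cannot be displayed immediately after admission.

`alpha = 0.05` for the Friedman gate is a default, not an estimate. Note the
interplay of the gates: the Friedman test detects *ordered* change across the
hour, the CV gate detects *magnitude* of variability; either alone admits
windows the other rejects (a high-variance but rank-balanced window passes
Friedman; a tiny monotone drift passes CV).

## Feature extraction

For each CPOT assessment at minute `t` (at or after baseline establishment),
the window `[t - 60, t)` of each model vital is extracted; here the coverage
gate is *strict* (more than 90%). With `d(u) = v(u) - baseline_v`, the
features per vital are: the value at the window end, the deviation at the
window end, the trapezoidal integrals of `max(d, 0)` and `max(-d, 0)`
(unit-minutes above/below baseline), and the mean deviation. The exact
deviation formulary of the original workflow is not published in an
accessible form; this five-quantity set is a declared superset covering both
stated ingredients (areas about the baseline and the difference from it) plus
the raw value. Sex, stratified age (20-44, 45-64, 65+) and the RASS score are
appended; RASS is taken from the same assessment or the nearest one within
±60 min (RASS is charted at least as often as CPOT in practice), otherwise
the assessment is dropped and logged. The label is positive iff CPOT ≥ 3.

The half-open window `[t - 60, t)` was chosen so that the features never peek
at the assessment minute itself.

## Class imbalance and the model

Pain-positive assessments are rare (~3%). The positive class is oversampled
with ADASYN: each minority point receives a synthesis budget proportional to
the majority density among its 5 nearest neighbors (standardized continuous
feature space), and each synthetic point lies on the segment between the seed
point and one of its nearest minority neighbors. One-hot and ordinal fields
(sex, age group, RASS) are copied from the seed point — interpolating
categorical codes is meaningless. No R implementation of ADASYN was available
in the supported dependency set, so the algorithm is implemented here
directly.

The classifier is a probability random forest (`ranger`). Hyperparameters
(`n_estimators`, `max_depth`) are grid-searched by inner cross-validated
AUROC on training data only; the default single-point configuration
(17 trees, depth 14) is the selected operating point of the modeling study
this package operationalizes, and the wider grids
`{5, 10, 17, 25, 50} x {6, 10, 14, 18}` cover it. Two design rules prevent
leakage:

- **Oversampling happens inside training folds only.** Synthetic rows are
  flagged, and the cross-validation loop structurally asserts that no
  flagged row is ever scored in a validation fold. (Whether oversampling
  preceded or followed the fold split is ambiguous in the original
  description; inside-fold is the only leakage-safe reading.)
- **Folds split by patient by default.** Assessment-level splits place rows
  of the same patient — same baseline, same episodes, nearly identical
  windows — on both sides of the split. On a zero-effect synthetic cohort
  (vitals independent of the CPOT label) assessment-level splits yield a
  spurious held-out AUROC around 0.65, while patient-level splits stay near
  0.5. The assessment-level option is retained for fidelity experiments only.

A patient-level split has a second-order consequence worth knowing: under a
null cohort the held-out AUROC scatters around chance with a spread of
several points rather than pinning to 0.50. Two mechanisms contribute in
opposite directions: per-patient constants (raw values, demographics) let
the forest memorize the *identity* of positive patients, which generalizes
slightly below chance to held-out patients; and with only ~50
positive-contributing patients, chance demographic imbalances (say, positive
patients happening to be older) create genuine within-cohort associations
that generalize slightly above chance. Both are properties of
cluster-held-out evaluation at finite cohort size, not bugs; comparisons
against chance should average over repeated fold seeds and allow a band of
roughly ±0.05.

## Evaluation

AUROC is computed as the pairwise concordance probability (ties counted 1/2),
banded as low (0.5-0.7), moderate (0.7-0.8) or high (≥ 0.8). Operating-point
metrics default to the Youden threshold, since no fixed threshold is part of
the method. The harmonic mean `2ab/(a+b)` summarizes sensitivity/specificity
pairs.

**Treatment response.** Around each fentanyl bolus (25-100 µg) at `t0`:
the pre-bolus CPOT is the last one in `[t0 - 120, t0]`, the post-bolus CPOT
the first in `(t0, t0 + 120]` (the 120-min search window is a stated
convention of this package). Boluses lacking either, with another analgesic
event within ±60 min, or without a pain index over the trajectory window are
excluded and logged. Boluses are grouped by CPOT improvement (decrease ≥ 1);
the pain index at `t0` vs `t0 + 60` is compared within groups (paired t,
two- and one-sided, plus Wilcoxon signed-rank) and between groups at
`t0 + 60` (Welch t plus rank-sum). The instantaneous minute `t0 + 60` is
used, not a short average. The original report cites Fisher's exact test for
a continuous-mean comparison, which is not executable as printed; the t/rank
tests are reported instead, without guessing the original intent.

## The synthetic cohort generator

No public data accompany the method, so validation rests on a generator whose
ground truth (true baselines, latent severity, responder status) is known.
Per patient and minute, each vital is

```
true baseline + drift * 2^(-t / half-life) + noise + pain_effect * severity
```

- **True baselines** are drawn from population means/SDs (HR 80±10 bpm,
  SBP 120±12 / DBP 65±7 mmHg, RR 16±2.5, SpO2 97±1%). MBP is always derived
  as DBP + PP/3 from an independent pulse-pressure channel (PP ≥ 5 mmHg), so
  DBP ≤ MBP ≤ SBP holds at every uncorrupted minute by construction.
- **Admission instability** is an exponentially decaying offset
  (HR +15 bpm, SBP +20, DBP +10 mmHg, RR +4, SpO2 -2%; half-life 15 min),
  guaranteeing the "unstable then stable" trajectory the baseline module
  expects.
- **Observation noise** is white by default (HR 3, SBP 5, DBP 3 mmHg-bpm
  scale, RR 1.5, SpO2 0.8 marginal SD); the temporal correlation of real
  vitals is carried by the structural components (drift, episodes), and an
  AR(1) coefficient is available for sensitivity analyses.
- **Pain episodes** arrive as a Poisson process (default ~0.8 onsets per
  48-h stay), never during the first 3 h (admission analgesia/sedation
  load), ramp up over 20 min and then *persist until treated or the record
  ends* — untreated ICU pain does not resolve on a minutes time scale. The
  persistence matters for validity checks: severity is locally flat around
  boluses, so any systematic pain-index drop after a bolus must come from a
  treatment response, not episode dynamics.
- **CPOT emission**: `CPOT = clamp(round(2 * severity + eps), 0, 8)` with
  observer noise `eps` uniform on {-1, 0, 1} — the simplest monotone map
  with rater disagreement. The episode amplitude scale is calibrated by
  bisection so the expected CPOT ≥ 3 fraction over all assessment minutes
  matches the target prevalence (3.3% by default). Assessments occur every
  8 h, within 5 min of each episode onset, and 60 min after each bolus (the
  clinical reassessment that gives every bolus a post-CPOT).
- **Boluses** trigger at CPOT ≥ 3 assessments (probability 0.5 by default, 1
  in treatment-response experiments), at least 120 min apart. Responders
  (default 30%) have severity multiplied by `max(0.3, 2^(-dt/30))` — halved
  within 30 min, floored at 0.3 — so the CPOT ≥ 3 probability genuinely
  falls; non-responders are unchanged.
- **Artifacts** corrupt a configurable fraction of minutes (2% default) with
  out-of-range spikes or swapped SBP/DBP, all removable by the plausibility
  rules; another 2% of minutes are dropped outright. RASS follows a slowly
  switching chain (mean dwell 4 h) with marginal mass concentrated at 0 and
  negative values, as in sedated ICU populations; it is independent of
  severity, so it acts as a realistic nuisance covariate.

What the generator does **not** emulate: pharmacokinetics (the responder
decay is phenomenological), sub-minute waveform structure, correlated
multi-organ deterioration, care-process feedback other than bolus-triggered
reassessment, and informative missingness (dropout is uniform). Passing
tests on this cohort therefore demonstrate that the pipeline recovers the
structure it assumes — they do not certify performance on real ICU data,
where the headline discrimination of the original study (AUROC ≈ 0.9 on
~10,000 patients) can only be approached with access to such data.

## Numerical conventions and degenerate inputs

- Timestamps are integer minutes since admission; windows are half-open
  `[a, b)`. A scheduled assessment may fall on the minute boundary after the
  last sample and reads the last sample.
- Coverage gates: baseline inclusive (≥ 0.90), feature window strict
  (> 0.90), matching the two source descriptions ("approximately 90%" vs
  "more than 90%").
- The Friedman statistic on a fully tied window (e.g. three identical
  segments) is defined as 0 with p = 1 (no evidence of difference); the
  tie-corrected statistic from `stats::friedman.test` is used otherwise.
- CV gate requires a positive window mean and is boundary-inclusive.
- First window acceptance wins; ties are impossible by construction.
- ADASYN falls back to uniform synthesis budgets when all minority
  neighborhoods are minority-pure, and refuses one-class inputs.
- Grid-search ties resolve to the first cell in grid order; all forests and
  fold assignments are explicitly seeded, so every pipeline stage is
  deterministic given its configuration.

## Problem sizes used in the validation suite

The test suite exercises the pipeline end to end at sizes chosen to give the
property checks adequate power while remaining routine to run: oracle
equivalence on 1,000 random instances; a 2,000-replicate type-I-error check
of the Friedman gate; baseline recovery on a 200-patient cohort; signal
detection on 500-patient cohorts (strong-effect vs zero-effect) under
patient-level 10-fold cross-validation with the mean taken over repeated
fold seeds; and treatment-response recovery on a 150-patient pain-rich
cohort (every positive assessment treated, 30% responders) plus twenty
20-patient zero-responder replicates for the null calibration of the
within-group drop test.

## Known limitations

- The plausibility ranges, CV thresholds, and deviation-feature set are
  configurable stand-ins where the original supplementary material is not
  accessible; conclusions that depend on their exact values should be
  checked by sensitivity analysis.
- The baseline is established once and never updated; slow physiological
  drift over long stays is absorbed into the deviation features.
- Calibration of the pain index (reliability of the probabilities) is out of
  scope; the index is validated for ranking and group contrasts.
- With patient-level splits and per-patient constant features, the null
  AUROC distribution is wide and not centered exactly at 0.5 (see above);
  comparisons against chance should use the empirical null, not 0.5 exactly.
- Baseline recovery against generator ground truth operates near its design
  tolerance (the anchor is a 5-min mean, the tolerance two of its standard
  errors), so the recovered fraction hovers around 95% with ~±1-point
  seed-to-seed scatter.
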