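# painindex

Baseline-adjusted, continuous visualization of pain in critically ill
patients from per-minute vital signs.

## The problem

ICU patients frequently cannot self-report pain; behavioral scales such as
the Critical-Care Pain Observation Tool (CPOT, 0–8) are charted only every
~8 hours by nursing staff, so pain between assessments goes unmeasured and
treatment may be delayed. Vital signs, however, are recorded every minute.
`painindex` implements a machine-learning pipeline that turns those streams
into a continuous **pain index** — the predicted probability that a
concurrent CPOT score would be ≥ 3 (the conventional pain-positive
threshold), displayed as 0–100%.

The core idea is *baseline adjustment*: each patient's vitals enter the model
as deviations from their own reference level, so inter-patient differences in
resting physiology do not masquerade as pain. Concretely, for vital
$v \in \{\mathrm{HR}, \mathrm{SBP}, \mathrm{MBP}, \mathrm{DBP}, \mathrm{RR}\}$
with per-patient baseline $b_v$ and deviation $d_v(u) = v(u) - b_v$ over the
hour before an assessment at time $t$:

- baseline $b_v$ = final 5-min mean of the first post-admission hour judged
  *stable* by three gates — ≥ 90% data coverage (with two-tailed linear
  completion), a Friedman rank test across three chronological 20-min
  segments ($p \ge \alpha$), and a coefficient-of-variation bound
  ($\mathrm{SD}/\mathrm{mean} \le$ per-vital threshold) — retried every
  20 min until all five vitals pass;
- features over $[t-60, t)$: $v(t^-)$, $d_v(t^-)$,
  $\int \max(d_v, 0)\,du$, $\int \max(-d_v, 0)\,du$ (trapezoidal,
  unit·min), and $\overline{d_v}$; plus sex, age group (20–44 / 45–64 / 65+)
  and the RASS sedation score;
- model: probability random forest (default 17 trees, depth 14, selected by
  grid search) with ADASYN oversampling of the rare positive class applied
  **inside** training folds only, and cross-validation split **by patient**;
- pain index = forest-predicted $P(\mathrm{CPOT} \ge 3)$, computable at any
  minute after baseline establishment;
- treatment response: around fentanyl boluses (25–100 µg), patients are
  grouped by CPOT improvement (decrease ≥ 1) and the pain index at the bolus
  vs 60 min later is compared within and between groups.

Because the clinical dataset behind the method is not public, the package
ships a synthetic ICU cohort generator with known ground truth (true
baselines, latent pain severity, bolus responder status) against which every
stage is validated end to end. See the methods vignette
(`vignettes/pain-index-methods.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(painindex)

cfg <- generator_config(n_patients = 60, duration_min = 1440, seed = 42)
cohort <- generate_cohort(cfg)
print(cohort)
#> Synthetic ICU cohort: 60 patients, 1440 min each
#>   vitals rows: 84662  assessments: 202 (2.5% CPOT >= 3)  boluses: 0

filtered <- apply_noise_filter(cohort$vitals)      # plausibility rules
#> (excluded 1631 implausible minutes, logged with the violated rule)

baselines <- establish_baselines(filtered$vitals)
print(baselines$objects[["P0001"]])
#> Baseline for P0001 established at minute 120 after 4 attempt(s)
#>     hr    sbp    mbp    dbp     rr
#>  68.41 127.36  90.51  72.09  18.04

features <- build_feature_table(filtered$vitals, baselines,
                                cohort$assessments, cohort$demographics)
#> feature table: 199 rows, 2.5% pain-positive

cv <- repeated_cv_auroc(features$features,
                        model_config(cv_folds = 5, cv_repeats = 2, seed = 42))
#> held-out AUROC 0.960 +/- 0.016 ("high" band)
```

The numbers read as follows: of 202 scheduled/event-triggered CPOT
assessments, 2.5% were pain-positive (the generator calibrates itself toward
a 3.3% prevalence; small cohorts scatter around it). Patient P0001's first
hour was rejected three times (coverage/drift/variability) before the window
ending at minute 120 passed all gates; the per-vital anchors are in that
patient's own units. With patient-level 5-fold cross-validation the deviation
features separate pain-positive from pain-negative assessments with held-out
AUROC ≈ 0.96 on this clean synthetic cohort — on real ICU data the
discrimination of this design is reported around 0.9.

A full run — simulate → filter → baseline → features → train → per-minute
prediction → evaluation → bolus-response analysis, with per-stage logs,
file hashes and a JSON manifest — is one call:

```r
run <- run_pipeline(pipeline_config(
  generator = generator_config(n_patients = 100, seed = 1),
  out_dir = "run1"))
```

A thin command-line wrapper is included at
`inst/scripts/painindex-pipeline.R` (`simulate` and `run-all` subcommands
with `--seed`, `--out`, `--config`).

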