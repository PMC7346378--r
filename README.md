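# strokeppm

Outcome-oriented **predictive process monitoring** for thrombolysis
decision support in acute ischemic stroke.

Deciding whether a stroke patient should receive intravenous rt-PA is a
time-critical call. Clinical guidelines state eligibility as indications and
contraindications, but real treatment decisions deviate from them, and the
guidelines cannot cover every patient. This package treats each hospital
admission as a *trace* in a clinical event log — a timestamped sequence of
activities (MRA, coagulation test, anti-platelet therapy, statin treatment,
...) with data payloads plus static case attributes — and predicts the
treatment outcome of a *running* case from its prefix, using classifiers
trained on completed, labelled historical cases. A computable rule engine
encodes the guideline itself, so model predictions can be compared and
audited against explainable guideline recommendations. It is aimed at
clinical-informatics researchers working with EMR-derived event logs.

## Method at a glance

* **Prefix logs.** A completed trace `⟨e₁,…,eₙ⟩` contributes its proper
  prefixes `⟨e₁⟩, ⟨e₁,e₂⟩, …, ⟨e₁,…,eₙ₋₁⟩` (a 5-event trace yields 4
  prefixes), so training instances look like the partial traces seen at
  prediction time.
* **Fixed-length encoding.** Over an ordered activity alphabet
  `L = ⟨A,B,C,D,E⟩`, the control flow of a prefix is encoded as per-activity
  frequencies (t1 = ⟨A,B,C,D,B⟩ ↦ ⟨1,2,1,1,0⟩); static case attributes pass
  through (categoricals one-hot); dynamic event attributes use *last-state*
  encoding — the payload at the activity's most recent occurrence (glucose
  5.1 then 8.3 on B ↦ 8.3). Vector length never depends on trace length.
* **Classifiers.** Decision tree and random forest (10 trees) with balanced
  class weights and a minimum-samples-per-leaf hyperparameter; stratified,
  group-aware 5-fold cross-validation (all prefixes of one case stay in one
  fold); accuracy, per-class precision/recall/F1 and midrank AUC.
* **Guideline engine.** The rt-PA IV 3-hour criteria (4 indications, 17
  contraindications, e.g. platelet count < 100·10⁹/L, glucose outside
  [2.8, 22.22] mmol/L, BP > 180/100 mmHg) ship as a declarative YAML rule
  set. Crossing recommendation with actual treatment labels each case into
  quadrant A (recommended, treated), B (not recommended, treated), C
  (recommended, untreated) or D (neither); B∪C is the nonconformant share.
* **Synthetic cohorts.** Because the motivating EMR data is private, a
  generator emulates its structure: snapshot marginals calibrated so the
  guideline recommendation rate matches the reference cohort prevalence (273/1191
  treated), a configurable nonconformance rate (default 12.6%), and
  class-conditional activity emission following the reference cohort's per-activity
  occurrence fractions.

## Worked example

```r
library(strokeppm)

## 1. simulate a cohort the size of the reference cohort
cohort <- generate_cohort(cohort_config(n_cases = 1191, seed = 42))
cohort
#> <synthetic cohort: 1191 cases, 273 treated, nonconformance 12.6% (A=198 B=75 C=75 D=843)>

## 2. guideline screening of one patient
evaluate_rules(patient_snapshot(age = 70, onset_to_consult = 2.5,
                                platelet_count = 99), builtin_ruleset())
#> <recommendation: not recommended>
#>   satisfied indications:       ind-1, ind-2, ind-3, ind-4
#>   violated contraindications:  contra-12

## 3. encode and cross-validate a random forest
enc <- encode_log(cohort$log, default_encoding_config(cohort$log),
                  label_name = "iv_thrombolysis")
cv  <- cross_validate(enc$x, enc$y, model_spec("random_forest", seed = 1),
                      k = 5, seed = 1)
round(cv$mean, 3)
#>   acc   precision_pos recall_pos  f1_pos   auc
#> 0.857           0.783      0.525   0.623 0.875   (plus the negative-class columns)
```

The cohort print shows the four conformance quadrants: 150 of 1191 cases
(12.6%) were treated against the recommendation (B) or denied a recommended
treatment (C). The patient in step 2 satisfies all four indications but is
blocked by contraindication 12 (platelet count below 100·10⁹/L). In step 3
the forest reaches AUC ≈ 0.87 on default conditions: the treatment label is
the guideline recommendation for 87.4% of cases, and the class-dependent
activity occurrences let the model partially recover the nonconformant rest.
`run_comparison()` produces the full DT/RF × with/without-control-flow ×
guideline table, and `inst/cli/strokeppm.R` exposes `simulate`,
`conformance` and `compare` subcommands for shell use.

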