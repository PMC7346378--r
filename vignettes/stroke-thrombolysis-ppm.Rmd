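---
title: "Predictive process monitoring for stroke thrombolysis: models, rules and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive process monitoring for stroke thrombolysis: models, rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeppm)
```

## The problem and the modelling frame

An acute-stroke admission produces a clinical event log: for each case
(patient) a timestamped sequence of activities — imaging, laboratory tests,
drug administrations — where events carry data payloads (a glucose value on
a lab event) and the case carries static attributes (age, onset-to-
consultation time, history flags). Whether the patient received
thrombolytic therapy is a boolean outcome of the completed case.
Predictive process monitoring asks: given only the *prefix* of a running
case, can we predict that outcome? This is early classification of complex
symbolic sequences: each element has an activity label, a timestamp and a
heterogeneous payload.

The package implements the full offline pipeline — prefix extraction,
fixed-length sequence encoding, classifier training and evaluation —
together with a computable encoding of the eligibility guideline the
decisions should nominally follow, and a simulator that stands in for the
protected EMR data.

## Prefix extraction

A completed trace of $n$ events contributes its proper prefixes of lengths
$1,\dots,n-1$; the complete trace is excluded by default
(`prefix_config(include_complete = FALSE)`) because at prediction time the
case is still running, so a 5-event trace yields 4 training prefixes.
Both bounds are configurable (`min_length`, `max_length`): long logs are
conventionally capped at 20-odd events to keep the prefix log from
swamping the trace count, though the acute-stroke control flow here is
short enough (7 activities) that no cap is needed. Every prefix inherits
its parent's case attributes and outcome label — the standard
outcome-oriented setup; labels describe the completed case, prefixes are
observations of it. Activity filtering to a clinically chosen subset (the
four acute-period activities) is an explicit configuration list rather
than an automated importance criterion: the package takes the selection as
an input.

## Sequence encoding

Three feature blocks, concatenated in a deterministic column order:

* **Control-flow frequencies** over an ordered alphabet fixed at
  configuration time. Alphabet order is first occurrence across the log in
  input order; an explicit alphabet can override this. Counting (rather
  than index or n-gram encoding) keeps the width independent of trace
  length, which is the property that lets prefixes of different lengths
  share one design matrix.
* **Static case attributes**: numerics pass through; logicals become 0/1;
  categoricals are one-hot over the categories observed when the encoding
  was fitted, with unseen test categories mapping to an all-zero block.
* **Last-state event attributes**: the payload value at the most recent
  occurrence of the activity — the latest snapshot of a dynamic
  measurement.

Missingness policy (the data source is silent on it, so it is explicit
here): frequencies are naturally zero for absent activities; numeric gaps
are filled with the fitted median, and last-state features additionally get
a companion `*_missing` indicator column, so "the lab was never run" stays
visible to the model. A `sentinel` policy (fixed fill value, no indicator)
is available for comparison.

Variance-based feature selection drops columns whose sample variance is
not strictly above a threshold; the default threshold 0 removes constants
only, since no stronger threshold is given by the source material.
Normalization is z-scoring with the *training* mean and sample (n−1) SD,
zero-SD columns passing through unchanged; it defaults to off because both
classifiers are trees and therefore scale-invariant. (Note the
pass-through convention: a constant column keeps its value rather than
being zeroed — transforming it would invent information.)

## Classifiers and evaluation

Decision trees (`rpart`, gini, `minbucket` = `min_samples_leaf`, cp fixed
at 0.001 so the leaf-size parameter is the operative regularizer) and
random forests (`ranger` probability forests, default 10 trees,
`min.node.size` = `min_samples_leaf`, single-threaded with an explicit seed
for bit reproducibility). Class weights are `balanced`
($w_c = n / (2 n_c)$) because treated cases are a ~23% minority.
`min_samples_leaf` defaults to 5 — a conventional middle value; the named
hyperparameter is exposed rather than grid-searched so runs stay
deterministic.

Splitting and cross-validation are **stratified and group-aware**: the unit
assigned to a side or fold is the parent case, never the individual prefix,
so no case's later prefix can leak into training while its earlier prefix
is in test. This is stricter than plain proportional sampling and is a
deliberate design choice.

Metrics follow the standard confusion-matrix definitions
($ACC=\frac{T_P+T_N}{T_P+F_P+T_N+F_N}$, $Recall=\frac{T_P}{T_P+F_N}$,
$Precision=\frac{T_P}{T_P+F_P}$, F1 their harmonic mean) computed twice:
once with the treated class positive, once with the untreated class
positive, since the two clinical decisions deserve separate error rates.
Zero-denominator cases report 0 and are flagged in `degenerate` instead of
erroring, so batch runs survive pathological folds. AUC is the midrank
(Mann–Whitney) statistic with half-credit ties; for a binary 0/1 scorer —
the guideline used as a classifier — this reduces in closed form to
balanced accuracy, $(Recall_{pos}+Recall_{neg})/2$. Cross-validation
reports per-fold metrics and their unweighted fold mean (confusion counts
are summed).

## The guideline engine

The rt-PA intravenous 3-hour eligibility criteria ship as a declarative
YAML rule set (`rtpa_iv_3h`): 4 indications, 17 contraindications, each
rule a single comparison/flag predicate or an `any_of` disjunction.
Decisions the narrative criteria leave open, resolved here and encoded in
the rule file:

* "Blood pressure > 180/100 mmHg" is read disjunctively — systolic > 180
  **or** diastolic > 100 — the clinically standard reading.
* Comparisons are strict as stated: a platelet count of exactly 100, INR
  1.7, PT 15 s, glucose 2.8 or 22.22 mmol/L is *not* contraindicated; the
  3-hour window is inclusive (a patient at exactly 3.0 h is in window).
* The "abnormal laboratory examinations" clause of contraindication 15 is
  a boolean input flag — no lab panel is defined for it upstream.
* Relative contraindications are out of scope, matching the reference
  cohort's own exclusion.
* Missing fields: under the default `strict` policy a recommendation is
  withheld and the missing fields are listed — absence of evidence must
  not enable a high-risk therapy. A `permissive` policy treats undecidable
  contraindications as non-violated for sensitivity analyses.

Every rule is evaluated (no short-circuit) so the returned explanation is
complete. Conformance crosses the recommendation with actual treatment
into quadrants A/B/C/D; the nonconformance percentage $100(B+C)/n$ is
rounded half-up to one decimal — note 151/1191 = 12.68% therefore prints
as 12.7.

## The synthetic cohort generator

The motivating cohort (1191 cases, 273 thrombolysed) is private, so the
generator emulates its *structure*, not its data:

* **Snapshot marginals** (all invented, all overridable): age truncated
  normal (68, 12) on [18, 95] years; onset-to-consultation lognormal
  (meanlog log 4.5, sdlog 0.8) truncated at 24 h; glucose lognormal with
  median 6 mmol/L; platelets truncated normal (220, 60)·10⁹/L; blood
  pressure bivariate normal (140/80, SDs 20/10, r = 0.6) mmHg; INR and PT
  truncated normals (1.05 ± 0.15, 12 ± 1.5 s); neurological-deficit score
  Binomial(9, 0.45); hard contraindication flags at 1% prevalence each,
  the two indication flags at 95% and 97%. These were calibrated
  analytically, once, so that the probability of a guideline
  recommendation equals the reference cohort's treated prevalence 273/1191 ≈ 0.229
  (the dominant factor is P(OTC ≤ 3 h) ≈ 0.31); they were not tuned
  afterwards.
* **Labels.** `guideline_faithful` (default): treatment equals the
  recommendation, then exactly `round(rate · n)` cases are flipped against
  it — default rate 0.126, split evenly between B-type flips (treated
  though not recommended) and C-type flips, because only the B+C total is
  known upstream, not the individual quadrants. `feature_logistic` draws
  labels from a logistic model in urgency/severity features;
  `label_noise` draws them independently of everything, as a null.
* **Events.** Seven activities in a fixed clinical order (admission, CT
  scan, blood draw, MRA, coagulation test, anti-platelet therapy, statin
  treatment) — three neutral placeholders completing the reference
  cohort's 7-activity control flow, whose remaining names are not available. Each of
  the four acute-period activities occurs with the reference
  cohort's class-conditional fractions (e.g. anti-platelet 8/128 in treated vs
  396/918 in untreated cases); timestamps are minute-resolution offsets
  in a 24-h admission window. The coagulation-test event carries a
  `glucose_lab` payload (case glucose + N(0, 0.3) noise) to exercise
  last-state encoding.

What passing tests on this simulator do **not** show: real EMRs have
missingness correlated with acuity, physiologic correlations beyond the
configured marginals, free-text fields, repeated activities, and label
noise that is anything but uniform. Results on synthetic cohorts validate
the machinery and its qualitative behaviour, not clinical performance.

Because activity emission conditions on the *actual* treatment label,
control flow carries information about guideline-nonconformant cases that
static attributes cannot explain — which is exactly why the
with-control-flow ablation outperforms the without-control-flow one on
this generator, mirroring the qualitative pattern reported for the real
cohort. Setting `p_treated = p_untreated` removes that channel.

## Numerical and interface conventions

* Determinism: every stochastic entry point takes a seed; `ranger` runs
  single-threaded; identical seeds give bit-identical cohorts, splits and
  forests.
* Timestamp ties sort stably in input order; duplicate event rows are
  legitimate data, not errors.
* CSV I/O is RFC-4180 via base R, ISO-8601 timestamps at second
  resolution; payload columns are typed by optional schema, else inferred
  (logical, then numeric, else categorical). Event/case round trips are
  exact for the value grids the generator emits (values rounded to ≤ 2
  decimals).
* Degenerate inputs: empty traces are invalid for prefix extraction but
  valid (all-zero frequency row) for encoding; traces emptied by activity
  filtering are retained for their case attributes; an empty keep set
  yields an empty alphabet.

## Problem sizes used by the test suite

Unit and property tests run at n of tens to a few thousand; the
end-to-end checks use 10,000 random snapshots for rule-engine/oracle
agreement and monotonicity, 10 seeds × 2,000 cases × 5-fold CV for the
coupled/null recovery checks, and 10 seeds × 800 cases for the
control-flow ablation — sizes chosen to put binomial noise well below the
asserted margins while keeping a desktop run in minutes.

## Known limitations

* The arterial-thrombolysis rule content is not bundled (its source
  criteria are not public); the engine accepts it as a user-supplied rule
  set.
* Free-text extraction (complaints, history narratives) is out of scope;
  the simulator emits structured fields directly.
* The per-quadrant counts A and D of the motivating cohort are not
  publicly determined (only B+C, A+B and C+D are), so the generator's
  even B/C split is a parameter, not a reproduction.
* Each activity occurs at most once per simulated trace; frequency
  encoding is exercised with counts > 1 only by the worked example and
  hand-built fixtures.
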