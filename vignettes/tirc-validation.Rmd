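---
title: "Validating the TIRC chest-radiograph decision rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the TIRC chest-radiograph decision rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tircval)
```

## The problem and the rule

Routine chest radiography (CXR) for every blunt-trauma patient has a low
diagnostic yield: in the cohort this package emulates, only 2.2% of 1518
blunt multiple-trauma patients had a traumatic intra-thoracic injury on
CXR.  The Thoracic Injury Rule-out Criteria (TIRC) is a checklist
decision rule meant to restrict imaging to a high-risk subset without
missing injuries.  A patient is flagged for CXR when either

* a **mandatory condition** holds — unstable hemodynamics or loss of
  consciousness — or
* **any one** of a set of history/exam criteria is present.

Two criterion lists circulate for TIRC.  The list that generated the
published screening characteristics (shipped as variant `"tirc-table2"`,
the default) is: age over 60, crepitation on auscultation, loss of
consciousness, decreased pulmonary sounds, chest wall pain, chest wall
tenderness, dyspnea, and thoracic skin abrasion.  The shorter list from
the model description (`"tirc-methods"`) omits the chest-wall pain and
tenderness items and the double-listed loss of consciousness.  The
source texts do not reconcile the two; both are available and neither is
asserted to be "the" rule.  Double-listing loss of consciousness as both
a mandatory condition and a checklist item is harmless under OR
semantics and is kept.

The age criterion defaults to `age >= 60` because the cohort's baseline
table bins age at "< 60 / >= 60" (50 patients at or above 60), although
prose descriptions say "over 60"; `age_comparison = "strictly_greater"`
switches to the strict reading.  Hemodynamic instability is a recorded
boolean rather than a value derived from blood pressure: the validation
cohort enrolled only stable, conscious patients, so no threshold choice
can affect the reproduced screening table.

```{r rule}
rule <- tirc_rule()      # the 8-item "tirc-table2" variant
rule
```

## Screening characteristics and interval methods

With rule decision cross-classified against the CXR outcome
(TP/FP/FN/TN), the package reports sensitivity, specificity, PPV, NPV,
prevalence, rule-positive rate, accuracy, and the likelihood ratios
PLR = sens/(1 − spec), NLR = (1 − sens)/spec.

Proportion confidence intervals default to the **continuity-corrected
Wilson** (Newcombe) score interval.  The choice is empirical: the source
study never names its interval method, and among the candidates
implemented here (`wilson_cc`, `wilson`, `clopper_pearson`) only the
continuity-corrected Wilson reproduces all four published proportion
intervals — (87.0, 100.0), (78.0, 82.1), (7.1, 14.0), (99.6, 100.0) —
at the printed 1-decimal rounding.  Likelihood-ratio intervals use the
standard log method, `exp(log(LR) ± z·SE)`, which reproduces the
published PLR interval (4.5, 5.6).  When a likelihood ratio is exactly
zero (a rule with no false negatives) the log method is undefined; the
degenerate interval (0, 0) is returned with a warning, matching the
published NLR row.

Display rounding is half-up at 1 decimal (2 decimals for the Brier
score); all internal computation and all stored JSON values are full
precision, with display-rounded twins stored alongside so rounding
policy never contaminates downstream comparisons.

```{r screening}
ct <- new_confusion_table(tp = 33, fp = 295, fn = 0, tn = 1190)
screening_report(ct)
```

The design-stage sample-size helper implements the single-proportion
precision formula `ceiling(z^2 p (1-p) / d^2)`.  For the study's stated
inputs (expected prevalence 6.5%, absolute precision 1.5%, 95%
confidence) it returns 1038, whereas the study states 1043; the source
of the extra five (z rounding, software default, attrition allowance) is
unstated, and a quoted "90% power" plays no role in a precision-based
calculation.  The formula is implemented as stated; the discrepancy is
documented, not patched.

## Discrimination, calibration, overall performance

`roc_from_scores()` builds the empirical ROC by sweeping thresholds over
the distinct score values (ties grouped), and `auc()` integrates it by
the trapezoidal rule, which equals the tie-corrected Mann–Whitney
statistic.  For a single binary rule the curve has one interior
operating point and the AUC is analytically (sensitivity +
specificity)/2 — 0.9007 for the reproduced table.  The published AUC of
0.95 cannot arise from the 2×2 table alone and the score that fed the
published curve (possibly a criteria count) is not recoverable from the
printed data; the package therefore validates its ROC machinery against
a brute-force pairwise oracle and the analytic binary identity instead
of targeting 0.95.  A criteria-count score (`score_kind = "count"`;
mandatory-only positives scored 1 so that thresholding at ≥ 1 reproduces
the rule decision) is available for multi-point curves.

The Brier score is the mean squared difference between predicted
probability and binary outcome, with the Murphy decomposition computed
over strata of distinct prediction values: reliability − resolution +
uncertainty, where uncertainty is prevalence × (1 − prevalence).  The
default prediction construction is `stratum_rate`: each patient is
assigned the observed injury rate of their rule stratum (33/328 if
flagged, 0/1190 if not).  This is the only construction that yields the
published Brier of 0.02 from the published table (binary 0/1 predictions
give 0.194), and it is also the natural probability a checklist rule
supports without a fitted model.  Its reliability term vanishes by
construction, so `scaled_reliability` (defined here as
reliability/uncertainty) is 0 on the fixture; the published "scaled
reliability 0.0002" has no stated formula and is not targeted.

Calibration is assessed as a count-weighted least-squares line through
the per-stratum (predicted, observed) points, matching the scatter-plot
description of the source study; perfect calibration is intercept 0,
slope 1.  With stratum-rate predictions the fixture's strata sit exactly
on the diagonal, so the fitted line is the reference line and, with only
two strata, the fit is saturated and its CIs are undefined (`NA`).  The
published intercept 0.1 / slope 1.7 would require patient-level
predicted probabilities that the printed data do not contain; instead
the fitting machinery is validated by parameter recovery — injecting a
known intercept/slope into binomially sampled 5-stratum data and
checking CI coverage across seeded replicates.  A patient-level logistic
recalibration (`calibration_logistic()`) is provided as a clearly
labelled alternate mode on the logit scale.

## The synthetic cohort generator

No patient-level data accompany the source study, so the generator
reproduces its *printed structure* and is itself first-class, tested
code.

**Fixture mode** is deterministic constraint satisfaction: the cohort
classifies to exactly the target cross-classification (default TP 33,
FP 295, FN 0, TN 1190 in n = 1518).  Rule-negative records carry no
checklist finding, are under the age threshold, have GCS 15 and stable
hemodynamics; every rule-positive record carries at least one criterion.
Criteria are spread over the rule-positives by largest-remainder
apportionment proportional to the published marginal counts (age ≥ 60:
50, GCS < 15: 50, chest wall tenderness: 107, skin abrasion: 104,
dyspnea: 42, decreased pulmonary sounds: 37, crepitation: 16), then
topped up to those exact counts, so the default fixture also reproduces
the published baseline table for every usable row.  The true joint
distribution of criteria among rule-positives is unprinted;
proportional allocation is an assumption, stated as such.

Two published figures are knowingly set aside.  The baseline table's
"chest wall pain 732/2173" row sums to nearly twice the cohort and
conflicts with prose ("401 (26.4%) had chest pain"); it is unusable, so
the chest-wall-pain criterion defaults to weight 0 (absent in the
fixture) while remaining part of the rule definition.  And the results
prose gives a mechanism mix (42.1% motor vehicle collisions, 28.2%
falls) that contradicts the abstract and the baseline table (78.8%,
13.6%); defaults follow the table's printed counts 1196/207/115.

Demographics and vitals are drawn from the published means ± SD (age
33.53 ± 15.42 truncated at 15; SBP 119.2 ± 9.1, DBP 78.2 ± 14.9, SpO2
97.7 ± 2.9, respiratory rate 13.6 ± 1.8, truncated to physiologic
ranges) with exact counts for sex (1220 male) and the non-criterion
findings (distracting pain 399, chest deformity 8, abdominal tenderness
25).  Only means and SDs are printed, so vitals are independent
truncated normals: real vital signs are correlated, and the generator
makes no claim to that dependence structure.  Passing tests on these
cohorts demonstrates correctness of the *rule and the evaluation
machinery*, not performance of TIRC on any real population.

**Stochastic mode** samples each patient independently: outcome with
prevalence 33/1518, rule stratum with P(rule+ | injured) = 1 and
P(rule+ | uninjured) = 295/1485, criteria as in fixture mode but by
per-criterion Bernoulli draws.  It matches the confusion table in
expectation and is used to check that replicate-averaged sensitivity
and specificity recover the published operating point.

All randomness flows through a single integer seed, recorded in the
cohort's provenance; generation restores the caller's RNG state.

```{r generator}
cohort <- generate_fixture(cohort_spec(), seed = 1)
confusion_table(classify_cohort(cohort), cohort)
```

## Numerical and design notes

* **Degenerate inputs.** Zero denominators raise typed undefined-metric
  errors naming the metric; an all-one-outcome ROC is refused; constant
  scores yield the degenerate diagonal; a PLR with specificity 1 is
  reported as infinite and its log-method CI refused; `lm`-based
  calibration with two strata returns `NA` intervals.
* **Ties.** ROC thresholds sweep distinct score values with ties
  grouped; tied pairs count one half in the U-statistic cross-check.
* **Rounding.** Half-up, display only (`round_half_up()`); banker's
  rounding would turn e.g. 10.05 into 10.0 and break agreement with
  printed 1-decimal values.
* **Problem sizes.** Tests run the full n = 1518 fixture (well under a
  second per generation), 200 stochastic replicates for the
  operating-point recovery, 100 seeded replicates for calibration CI
  coverage, and exhaustive 2^10 enumeration of the binary predicate
  space for the rule; these sizes were chosen to make the statistical
  assertions sharp at negligible cost.
* **Complete cases only.** The CSV layer rejects blanks rather than
  imputing; the emulated study analysed complete cases and the schema
  has no missing-data semantics.

## Limitations

The generator reproduces marginal structure, not real inter-criterion
correlation or injury-type-specific prevalence.  The published AUC
(0.95), calibration intercept/slope (0.1, 1.7) and scaled reliability
(0.0002) depend on patient-level constructions the source does not
print, and are demonstrably out of reach of the 2×2 table; they are
replaced by property-based validation of the corresponding machinery.
Inter-rater agreement, CT confirmation workflow, and comparison with the
NEXUS-chest rule are out of scope.
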