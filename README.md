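# tircval

Validation toolkit for the **Thoracic Injury Rule-out Criteria (TIRC)**,
a checklist clinical decision rule that selects blunt multiple-trauma
patients who need a chest radiograph (CXR).  Routine CXR for every
trauma patient has low yield — in the cohort this package emulates, only
33 of 1518 patients (2.2%) had a traumatic intra-thoracic injury — so a
rule that safely rules out imaging matters.  `tircval` is aimed at
researchers who build or validate diagnostic decision rules and want the
full accuracy-assessment battery in one tested package.

## The rule and the statistics

A patient is TIRC-positive (CXR indicated) when a mandatory condition
holds (unstable hemodynamics, loss of consciousness) **or** any one of a
checklist of criteria is present — default list: age ≥ 60, crepitation,
loss of consciousness, decreased pulmonary sounds, chest wall pain,
chest wall tenderness, dyspnea, thoracic skin abrasion.

Cross-classifying the rule against the CXR outcome gives the 2×2 table
(TP, FP, FN, TN) from which the package computes

* sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV, NPV,
  prevalence, rule-positive rate, accuracy — with continuity-corrected
  Wilson (Newcombe) confidence intervals by default (plain Wilson and
  Clopper–Pearson available);
* PLR = sens/(1−spec) and NLR = (1−sens)/spec with log-method
  (Simel) intervals, `exp(log(LR) ± z·SE)`;
* the empirical ROC curve and trapezoidal AUC (= the tie-corrected
  Mann–Whitney statistic; (sens+spec)/2 for a binary rule);
* the Brier score with Murphy decomposition
  (reliability − resolution + uncertainty) over strata of distinct
  predicted probabilities;
* a count-weighted least-squares calibration line through the
  per-stratum (predicted, observed) points (perfect calibration:
  intercept 0, slope 1), plus logistic recalibration;
* the single-proportion precision sample-size formula
  `ceiling(z²·p(1−p)/d²)`.

Because no patient-level data are published, a synthetic-cohort module
generates study-structured cohorts: a deterministic **fixture** that
classifies to an exact target table (default TP 33 / FP 295 / FN 0 /
TN 1190) while matching the published baseline marginals, and a seeded
**stochastic** sampler matching them in expectation.  See the methods
vignette (`vignettes/tirc-validation.Rmd`) for the modelling choices and
their limits.

## Worked example

```r
library(tircval)

cohort <- generate_fixture(cohort_spec(), seed = 1)   # 1518 patients
triage <- classify_cohort(cohort, tirc_rule())        # default 8-item rule
ct     <- confusion_table(triage, cohort)
screening_report(ct)
```

```
Screening performance (95% CI, wilson_cc)
             metric              display
        sensitivity 100.0 (87.0 - 100.0)
        specificity   80.1 (78.0 - 82.1)
                ppv    10.1 (7.1 - 14.0)
                npv 100.0 (99.6 - 100.0)
         prevalence      2.2 (1.5 - 3.1)
 rule_positive_rate   21.6 (19.6 - 23.8)
           accuracy   80.6 (78.5 - 82.5)
                plr      5.0 (4.5 - 5.6)
                nlr      0.0 (0.0 - 0.0)
TP 33  FP 295  FN 0  TN 1190  (n = 1518)
```

Every injured patient is flagged (sensitivity 100%, NLR 0 — the rule's
rule-out purpose), while only 328/1518 (21.6%) would be imaged; a
positive flag multiplies the odds of injury five-fold (PLR 5.0) but
most flags are still false alarms (PPV 10.1%).

```r
p <- stratum_predictions(triage, cohort)      # stratum injury rates
brier_score(p, cohort$cxr_positive, "stratum_rate")
```

```
Brier score: 0.0196  (n = 1518, predictions: stratum_rate)
  reliability 0.000000 - resolution 0.001715 + uncertainty 0.021267
  scaled reliability: 0.000000
```

One call runs the whole pipeline and (optionally) writes a JSON report,
ROC/calibration point CSVs and a log:

```r
bundle <- run_pipeline(run_config(input = "fixture", seed = 1,
                                  output_dir = "tirc-out"))
```

A command-line front end with subcommands `simulate`, `classify`,
`evaluate`, `report`, `all` lives at `inst/scripts/tirc-report.R`:

```sh
Rscript inst/scripts/tirc-report.R all --seed 1 --out-dir tirc-out
```

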