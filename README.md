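# thyverify

Diagnostic performance and clinical utility of binary thyroid molecular
classifiers under **partial verification**.

## The problem

Indeterminate thyroid nodules (Bethesda III/IV cytology) are increasingly
triaged with binary molecular classifiers: a negative call supports
surveillance, a positive call supports diagnostic surgery. Because the
reference standard — surgical histopathology — is obtained almost only when
the test is positive (~90% of positives operated vs ~5% of negatives in the
real-world cohorts this package targets), the operated-only 2×2 table is
distorted by verification bias: specificity collapses and prevalence is
inflated. `thyverify` is for biostatisticians and clinical researchers
evaluating such classifiers from nodule-level cohort data.

## The method

The package implements the Hall/Bayes-theorem correction used in real-world
validation studies. An externally established sensitivity Se_ext is applied
to the n unoperated test-negative nodules:

    FN_imp = round(n · (1 − Se_ext)),   TN_imp = n − FN_imp

and the six performance metrics (Se, Sp, PPV, NPV, accuracy, prevalence) are
recomputed on the augmented table

    Se  = TP / (TP + FN_obs + FN_imp)
    Sp  = (TN_obs + TN_imp) / (TN_obs + TN_imp + FP)
    NPV = (TN_obs + TN_imp) / (TN_obs + TN_imp + FN_obs + FN_imp)

each with a Clopper–Pearson exact interval. NIFTP counts as malignant
(positive calls on NIFTP are true positives). Around this core the package
provides cohort CSV ingestion/validation with the study exclusion rules,
descriptive and histopathology tabulations, decision-support concordance and
counterfactual surgery-avoidance rates, and a synthetic cohort generator
with test-result-dependent surgery selection for bias experiments. Naive
(operated-only) and adjusted results are always reported side by side.

## Worked example

The bundled synthetic study-replica cohort (256 nodules, exact at every
tallied margin of the cohort it emulates):

```r
library(thyverify)
csv <- system.file("extdata", "study_cohort_synthetic.csv", package = "thyverify")
cohort  <- read_cohort(csv)
excl    <- apply_exclusions(cohort)
verified <- tally_verified(excl$cohort)
adjusted <- adjust_counts(verified, adjustment_config(external_sensitivity = 0.946))
print(adjusted)
#> verification-adjusted 2x2 (imputed cells marked *):
#>   TP 49           FP 29
#>   FN 8* + 2 (10)  TN 142* + 5 (147)
#>   external sensitivity 0.946, rounding nearest

compute_performance(adjusted)
#> diagnostic performance (adjusted mode; 95% Clopper-Pearson CIs)
#>   2x2: TP 49  FP 29  FN 10  TN 147  (N = 235)
#>   Sensitivity        83.1% (71.0-91.6)  [49/59]
#>   Specificity        83.5% (77.2-88.7)  [147/176]
#>   PPV                62.8% (51.1-73.5)  [49/78]
#>   NPV                93.6% (88.6-96.9)  [147/157]
#>   Accuracy           83.4% (78.0-87.9)  [196/235]
#>   Disease prevalence 25.1% (19.7-31.2)  [59/235]

clinical_utility(flow_counts(excl$cohort), adjusted)
#> clinical utility
#>   decision support, test-negative    95.5 (91.0-98.2)  [150/157]
#>   decision support, test-positive    89.8 (81.5-95.2)  [79/88]
#>   overall concordance                93.5 (89.6-96.2)  [229/245]
#>   surgeries avoided                  63.6 (57.1-69.7)  [150/236]
#>   potentially unnecessary avoided    79.5 (72.8-85.2)  [140/176]
```

Reading: of 157 test-negative nodules, 150 were managed without surgery; the
imputation splits those 150 into 142 theoretical benign and 8 theoretical
missed cancers, giving an adjusted NPV of 93.6% — the residual malignancy
risk behind a negative call is ~6%. Under the counterfactual that all 236
nodules (excluding the 9 unoperated positives) would otherwise have been
resected, 63.6% of surgeries and 79.5% of *potentially unnecessary*
surgeries (benign pool of 176, of which 36 were operated: 29 false
positives, 5 operated true negatives, 2 NIFTP) were avoided.

`run_analysis(csv, output_dir = "out/")` runs the whole pipeline and writes
`report.json` (full precision) plus `report.md` (formatted); a thin CLI
wrapper lives at `inst/cli/thyverify.R`. `simulate_cohort(sim_params())` and
`bias_experiment()` generate cohorts with the same selection structure and
quantify how the adjustment removes the specificity bias (see the methods
vignette, including why the adjusted NPV is *not* the closed-form Bayes NPV).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the study-replica cohort from scratch with the installed package,
runs exclusions → verified tally → imputation (Se_ext = 0.946, nearest
rounding) → adjusted performance, and writes the adjusted sensitivity,
specificity, NPV, accuracy and prevalence (as full-precision percentages)
and the imputed theoretical-benign count to the JSON file.
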