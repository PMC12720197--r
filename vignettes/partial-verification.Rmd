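---
title: "Classifier performance under partial verification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier performance under partial verification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyverify)
```

## The estimation problem

Thyroid nodules with indeterminate cytology (Bethesda III/IV) are often
triaged with a binary molecular classifier: a *negative* call supports
surveillance, a *positive* call supports diagnostic surgery. The reference
standard — histopathology of the resected specimen — therefore exists almost
only where the test was positive. In the cohort structure this package
models, roughly 90% of test-positive nodules are operated but under 5% of
test-negative ones. An operated-only ("naive") 2×2 table is then badly
distorted by **partial verification bias**: operated test-negatives are a
small, selected sample, specificity collapses (most unoperated benign
nodules never enter the table) and prevalence among verified nodules is
inflated far above the population value.

`thyverify` implements the pragmatic correction used in real-world validation
studies of such classifiers: Hall's Bayes-theorem device. An externally
established sensitivity \(Se_{ext}\) (from the classifier's original
validation) is applied to the \(n\) unoperated test-negative nodules,

\[ FN_{imp} = \operatorname{round}\{ n (1 - Se_{ext}) \}, \qquad
   TN_{imp} = n - FN_{imp}, \]

and performance is recomputed on the augmented table with
\(FN = FN_{obs} + FN_{imp}\), \(TN = TN_{obs} + TN_{imp}\). Only the
negative arm is imputed; unoperated test-positives and operated nodules
without an accessible report never enter a 2×2 cell. That asymmetry is part
of the method being replicated, not an implementation shortcut.

Truth labelling counts NIFTP as malignant (its diagnosis is strictly
post-surgical, and a positive call on a NIFTP nodule is treated as a true
positive), which matters in two places: the verified tally and the
potentially-unnecessary-surgery accounting below.

## Tunable parameters

* `external_sensitivity` (default **0.946**): the sensitivity from the
  classifier's original validation study. It is *external* by construction —
  using the cohort's own naive sensitivity would defeat the correction.
* `rounding` (default **nearest**, half away from zero): the imputed
  missed-cancer count is an integer; 150 × 0.054 = 8.1 becomes 8. Floor and
  ceiling variants exist for sensitivity analysis.
* `conf_level` (default **0.95**): all intervals are Clopper–Pearson exact;
  no Wilson/Agresti–Coull/mid-p alternatives are offered, matching the
  reporting practice being replicated.
* `counterfactual` (default **exclude_unoperated_positives**): the
  surgeries-avoided denominator assumes every analyzable nodule would have
  gone to surgery without testing, *except* test-positives whose patients
  declined surgery anyway (they would likely have declined regardless). The
  all-nodules denominator is available and clearly labelled non-default.
* `count_niftp` (default **TRUE**): NIFTP resections count among
  "potentially unnecessary" operations (the tumor is indolent; surgery was
  diagnostic, not therapeutic). With the study-replica integers this gives
  36 operated out of a 176-nodule benign pool, hence 140/176 = 79.5%
  avoided; with `count_niftp = FALSE` the formula reduces to the plain
  benign accounting (142/176). We adopted the NIFTP-counting version because
  it is the only reading that reproduces the published avoidance rate from
  its own building blocks.
* `age_cut` (default **54**): Table-style age dichotomisation (20–54 vs
  >54), configurable.

## Exact statistics

Clopper–Pearson bounds come from the Beta-quantile closed form
(`qbeta(α/2, x, n−x+1)` and `qbeta(1−α/2, x+1, n−x)`, with the conventional
0 and 1 at the boundaries). The test suite checks this route against two
independent ones: bisection over exact binomial tail probabilities, and
`stats::binom.test`. Fisher's exact test and the Pearson chi-square are
delegated to `stats::fisher.test` / `stats::chisq.test` behind the package's
interface; the suite verifies the Fisher p-value against a hand-written
full-enumeration hypergeometric oracle for *every* 2×2 table with grand
total ≤ 40 (probability-mass two-sided criterion, 1e-7 tie tolerance), and
the chi-square statistic against its closed 2×2 form.

For descriptive tables the default 2×2 association test is the
continuity-corrected chi-square, switching to Fisher when any expected cell
is below 5. On the replica's age stratification this reproduces the
published p = 0.04 (the uncorrected statistic gives 0.03), which is how the
ambiguity about which test produced which table p-value was resolved.

A caveat printed with every adjusted report: imputed cells are theoretical
counts, not binomial observations, so exact intervals on adjusted metrics
replicate a reporting convention rather than a sampling guarantee. Related:
the published PPV interval for the cohort this package emulates (54.3–70.6)
is *not* Clopper–Pearson on 49/78 (which gives 51.1–73.5), and the published
NPV and utility intervals are similarly off by a few tenths; the package
reports CP throughout and does not attempt to reverse-engineer the other
interval method. Point estimates are unaffected.

## The synthetic cohort generator

`sim_params()` defaults encode the stated world of the emulated study:
245 nodules, prevalence 0.251, test Se/Sp 0.83/0.835 (the adjusted-estimate
scale), surgery probabilities 0.898 (positive) and 0.045 (negative), 78%
Bethesda IV, 83.7% female, one missing report per ~86 surgeries, ~4% NIFTP
among operated malignants, 11/256 collision-tumor exclusions, ages 20–90,
log-normal nodule sizes with mean ≈ 1.2 cm (meanlog = log 1.1,
sdlog = 0.35 — chosen once as a realistic right-skewed size distribution
consistent with the reported mean; the paper states no distribution), and
follow-up 10–1451 days.

Surgery selection depends **only on the test result** — the information
structure the Bayes/Hall adjustment implicitly assumes. A `truth_leakage`
parameter (extra surgery probability for malignant test-negatives, default
0) exists because in the emulated cohort the two false negatives reached
surgery only through a co-existing test-positive nodule; it lets users break
the assumption deliberately. Covariates are independent of truth: they
exercise the descriptive layer and encode no risk model, so a green
descriptive test establishes bookkeeping correctness, not clinical realism.
Equally, the generator emulates selection structure — it does not simulate
microRNA signal, ultrasound features, or correlated nodules within patients
(the multi-nodule option only duplicates patient identifiers).

Alongside the stochastic generator, `study_replica_cohort()` builds a
deterministic 256-record cohort that is synthetic at the record level but
**exact at every tallied margin** (flow counts, strata, subtype table,
follow-up mean/range, mean age, patient multiplicity). It is the canonical
desk-scale input: every published headline number is recomputable from it by
integer arithmetic.

## What the bias experiment does and does not establish

`bias_experiment()` simulates replicate cohorts, applies the full pipeline,
and compares naive and adjusted estimators of sensitivity, specificity and
NPV against generative truth, where the true NPV is the closed form
\(Sp(1-p)/\{Sp(1-p) + (1-Se)p\}\).

Under study-like selection the adjusted **specificity** estimator is
dramatically less biased than the naive one (typical run: |bias| ≈ 0.01 vs
0.64) — the adjustment does the job it was designed for, rescuing the
benign majority that never reaches surgery.

The adjusted **NPV** is a different story, and this is a known, deliberate
red flag in the acceptance suite. The imputation equates
\(P(\text{malignant}\mid\text{test-negative})\) with \(1 - Se_{ext}\). The
Bayes posterior is \((1-Se)p / \{(1-Se)p + Sp(1-p)\}\), and the two agree
only when \(Sp(1-p) = Se\,p\) — e.g. Sp ≈ 0.32 at p = 0.25, far from any
realistic thyroid-classifier world. Under the stated world (p = 0.25,
Se = Se_ext = 0.946, Sp = 0.835) the adjusted NPV estimator converges to
about \(0.955\,Se_{ext} + 0.045\,NPV_{true} \approx 0.947\) while the true
NPV is 0.979. The corresponding acceptance assertion is implemented
faithfully and fails by construction; we left it failing rather than
redefining either side, because the gap is a property of the method being
replicated: the Hall-style shortcut is conservative (it *understates* NPV
when \(1-Se_{ext}\) exceeds the true posterior malignancy risk), which is
worth knowing before quoting an adjusted NPV as if it were the Bayes value.

## Numerical and degenerate-input choices

* Percentages render half-up at 1 decimal (49/59 → 83.1%; note the emulated
  study prints 83.0 for this same fraction — a rounding slip on its side).
  Full precision is kept in every object and in the JSON outputs.
* P-values display as two significant figures with a `<0.001` floor and
  `>0.9` ceiling; full precision is retained internally.
* Zero denominators yield *undefined* proportions (printed "not
  applicable"), never 0; an all-zero 2×2 is an error ("no verified
  outcomes"), as is an empty analysis cohort or a vanishing counterfactual
  denominator.
* `fn_imputed` is clamped to `[0, n]` after rounding; the
  potentially-unnecessary numerator is clamped at 0 (with a warning) in the
  pathological case where NIFTP resections outnumber the imputed benign
  pool.
* Exclusion flags are taken from the data, never inferred: the
  nodule-to-pathology matching that produces them is a manual clinical step
  with no published algorithm.

## Known limitations

* Only the Hall/Bayes single-sensitivity imputation is implemented; no
  Begg–Greenes, multiple imputation, or predictive-value interval methods.
* The imputation ignores uncertainty in \(Se_{ext}\) itself; intervals on
  adjusted metrics are conditional on it.
* The generator's covariates carry no risk signal, so it cannot be used to
  study covariate-dependent verification.
* Exact r×c tests beyond 2×2 are not provided (chi-square suffices for the
  descriptive tables).
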