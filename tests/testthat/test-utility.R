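study_flow <- function() flow_counts(replica_analysis())
study_adjusted <- function() {
  adjust_counts(tally_verified(replica_analysis()), adjustment_config(0.946))
}

test_that("decision-support rates reproduce the study concordances", {
  ds <- decision_support(study_flow())
  expect_identical(c(ds$support_when_negative$numerator,
                     ds$support_when_negative$denominator), c(150L, 157L))
  expect_identical(c(ds$support_when_positive$numerator,
                     ds$support_when_positive$denominator), c(79L, 88L))
  expect_identical(c(ds$overall_concordance$numerator,
                     ds$overall_concordance$denominator), c(229L, 245L))
  # overall numerator = sum of the arm numerators
  expect_identical(ds$overall_concordance$numerator,
                   ds$support_when_negative$numerator +
                     ds$support_when_positive$numerator)
  expect_equal(round(100 * ds$support_when_negative$estimate, 1), 95.5)
  expect_equal(round(100 * ds$support_when_positive$estimate, 1), 89.8)
  expect_equal(round(100 * ds$overall_concordance$estimate, 1), 93.5)
})

test_that("decision support handles hand-tallied and degenerate flows", {
  mixed <- flow_counts(make_cohort(
    cohort_row("N1"), cohort_row("N2"), cohort_row("N3"),
    cohort_row("N4", surgery = TRUE, histology = "benign"),
    cohort_row("N5", test_result = "positive", surgery = TRUE,
               histology = "malignant"),
    cohort_row("N6", test_result = "positive")))
  ds <- decision_support(mixed)
  expect_equal(ds$support_when_negative$estimate, 3 / 4)
  expect_equal(ds$support_when_positive$estimate, 1 / 2)
  expect_equal(ds$overall_concordance$estimate, 4 / 6)

  concordant <- flow_counts(make_cohort(
    cohort_row("N1"),
    cohort_row("N2", test_result = "positive", surgery = TRUE,
               histology = "malignant")))
  ds2 <- decision_support(concordant)
  expect_equal(ds2$overall_concordance$estimate, 1)

  onearm <- flow_counts(make_cohort(cohort_row("N1")))
  ds3 <- decision_support(onearm)
  expect_false(ds3$support_when_positive$defined)
})

test_that("surgeries avoided uses the counterfactual denominator", {
  sa <- surgeries_avoided(study_flow())
  expect_identical(c(sa$numerator, sa$denominator), c(150L, 236L))
  expect_equal(round(100 * sa$estimate, 1), 63.6)

  all_den <- surgeries_avoided(study_flow(), counterfactual = "all")
  expect_identical(all_den$denominator, 245L)

  hand <- flow_counts(make_cohort(
    cohort_row("N1"), cohort_row("N2"), cohort_row("N3"), cohort_row("N4"),
    cohort_row("N5"), cohort_row("N6"), cohort_row("N7"), cohort_row("N8"),
    cohort_row("N9", test_result = "positive", surgery = TRUE,
               histology = "malignant"),
    cohort_row("N10", test_result = "positive", surgery = TRUE,
               histology = "benign")))
  expect_equal(surgeries_avoided(hand)$estimate, 8 / 10)

  none_avoided <- flow_counts(make_cohort(
    cohort_row("N1", surgery = TRUE, histology = "benign")))
  expect_equal(surgeries_avoided(none_avoided)$estimate, 0)

  # all positives unoperated: the counterfactual denominator vanishes
  degenerate <- flow_counts(make_cohort(
    cohort_row("N1", test_result = "positive")))
  expect_error(surgeries_avoided(degenerate), "denominator")
})

test_that("potentially-unnecessary accounting reproduces 140/176", {
  pu <- potentially_unnecessary_avoided(study_adjusted())
  expect_identical(c(pu$numerator, pu$denominator), c(140L, 176L))
  expect_equal(round(100 * pu$estimate, 1), 79.5)

  # without counting the NIFTP resections the numerator is the imputed TN
  pu2 <- potentially_unnecessary_avoided(study_adjusted(), count_niftp = FALSE)
  expect_identical(c(pu2$numerator, pu2$denominator), c(142L, 176L))
})

test_that("potentially-unnecessary edge cases and monotonicity", {
  base <- study_adjusted()
  modify <- function(a, ...) {
    a[names(list(...))] <- list(...)
    a
  }
  spared <- modify(base, tn_observed = 0L, fp = 0L, tp_niftp = 0L,
                   tn_imputed = 50L)
  expect_equal(potentially_unnecessary_avoided(spared)$estimate, 1)

  all_operated <- modify(base, tn_imputed = 0L, tp_niftp = 0L)
  expect_equal(potentially_unnecessary_avoided(all_operated)$estimate, 0)

  empty <- modify(base, tn_imputed = 0L, tn_observed = 0L, fp = 0L)
  expect_false(potentially_unnecessary_avoided(empty)$defined)

  vals <- vapply(c(0L, 10L, 50L, 142L, 300L), function(tn_imp)
    potentially_unnecessary_avoided(modify(base, tn_imputed = tn_imp),
                                    count_niftp = FALSE)$estimate,
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the utility report records its counterfactual assumptions", {
  u <- clinical_utility(study_flow(), study_adjusted())
  expect_identical(u$assumptions$counterfactual_denominator,
                   "exclude_unoperated_positives")
  expect_true(u$assumptions$niftp_resections_potentially_unnecessary)
  expect_equal(u$assumptions$external_sensitivity, 0.946)
  expect_identical(u$surgeries_avoided$numerator,
                   study_flow()$n_negative_unoperated)
})
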