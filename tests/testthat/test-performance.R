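study_verified <- function() tally_verified(replica_analysis())

test_that("verified tally assigns every record to one stratum", {
  v <- study_verified()
  expect_identical(
    unclass(v)[c("tp", "tp_niftp", "fp", "fn_operated", "tn_operated",
                 "n_negative_unoperated", "n_positive_unoperated",
                 "n_positive_no_histology")],
    list(tp = 49L, tp_niftp = 2L, fp = 29L, fn_operated = 2L,
         tn_operated = 5L, n_negative_unoperated = 150L,
         n_positive_unoperated = 9L, n_positive_no_histology = 1L))
  expect_identical(
    v$tp + v$fp + v$fn_operated + v$tn_operated + v$n_negative_unoperated +
      v$n_positive_unoperated + v$n_positive_no_histology +
      v$n_negative_no_histology,
    v$n_analyzable)

  no_surg <- tally_verified(make_cohort(cohort_row()))
  expect_identical(no_surg$tp + no_surg$fp + no_surg$fn_operated +
                     no_surg$tn_operated, 0L)
})

test_that("imputation splits unoperated negatives per the external sensitivity", {
  imp <- impute_unverified_negatives(150, adjustment_config(0.946))
  expect_identical(imp, list(tn_imputed = 142L, fn_imputed = 8L))

  expect_identical(impute_unverified_negatives(37, adjustment_config(1.0)),
                   list(tn_imputed = 37L, fn_imputed = 0L))
  expect_identical(impute_unverified_negatives(0, adjustment_config(0.7)),
                   list(tn_imputed = 0L, fn_imputed = 0L))
  expect_identical(
    impute_unverified_negatives(100, adjustment_config(0.5))$fn_imputed, 50L)

  # rounding rules around the .5 boundary: 150 * 0.05 = 7.5
  expect_identical(
    impute_unverified_negatives(150, adjustment_config(0.95, "nearest"))$fn_imputed,
    8L)
  expect_identical(
    impute_unverified_negatives(150, adjustment_config(0.946, "floor"))$fn_imputed,
    8L)
  expect_identical(
    impute_unverified_negatives(150, adjustment_config(0.946, "ceiling"))$fn_imputed,
    9L)

  # fn_imputed is non-increasing in the external sensitivity
  fns <- vapply(seq(0.5, 1, by = 0.01), function(se)
    impute_unverified_negatives(150, adjustment_config(se))$fn_imputed,
    integer(1))
  expect_true(all(diff(fns) <= 0))

  expect_error(adjustment_config(0), "external_sensitivity")
  expect_error(adjustment_config(1.2), "external_sensitivity")
})

test_that("adjusted counts combine observed and imputed cells", {
  adj <- adjust_counts(study_verified(), adjustment_config(0.946))
  expect_identical(adj$tp, 49L)
  expect_identical(adj$fp, 29L)
  expect_identical(adj$fn_observed + adj$fn_imputed, 10L)
  expect_identical(adj$tn_observed + adj$tn_imputed, 147L)
  expect_identical(adj$fn_imputed + adj$tn_imputed, 150L)

  # cohort conservation: cells + strata outside the 2x2 = analyzable size
  expect_identical(
    adj$tp + adj$fp + adj$fn_observed + adj$fn_imputed + adj$tn_observed +
      adj$tn_imputed + adj$n_positive_unoperated +
      adj$n_positive_no_histology + adj$n_negative_no_histology,
    245L)

  # full verification: imputation is a no-op
  full <- tally_verified(make_cohort(
    cohort_row("N1", test_result = "positive", surgery = TRUE,
               histology = "malignant"),
    cohort_row("N2", surgery = TRUE, histology = "benign")))
  adj_full <- adjust_counts(full)
  expect_identical(adj_full$fn_imputed + adj_full$tn_imputed, 0L)
})

test_that("adjusted performance reproduces the integer-arithmetic metrics", {
  perf <- compute_performance(adjust_counts(study_verified()))
  m <- perf$metrics
  frac <- function(p) c(p$numerator, p$denominator)
  expect_identical(frac(m$sensitivity), c(49L, 59L))
  expect_identical(frac(m$specificity), c(147L, 176L))
  expect_identical(frac(m$ppv), c(49L, 78L))
  expect_identical(frac(m$npv), c(147L, 157L))
  expect_identical(frac(m$accuracy), c(196L, 235L))
  expect_identical(frac(m$prevalence), c(59L, 235L))
  expect_identical(perf$mode, "adjusted")
})

test_that("naive performance exposes the verification bias", {
  perf <- compute_performance(study_verified())
  m <- perf$metrics
  expect_identical(c(m$sensitivity$numerator, m$sensitivity$denominator),
                   c(49L, 51L))
  expect_identical(c(m$specificity$numerator, m$specificity$denominator),
                   c(5L, 34L))
  expect_identical(perf$mode, "naive")
  # operated-only specificity collapses far below the adjusted estimate
  adj <- compute_performance(adjust_counts(study_verified()))
  expect_lt(m$specificity$estimate, adj$metrics$specificity$estimate)
})

test_that("degenerate tables are handled explicitly", {
  perfect <- compute_performance(structure(
    list(tp = 20L, tp_niftp = 0L, fp = 0L, fn_operated = 0L, tn_operated = 0L,
         n_negative_unoperated = 0L, n_positive_unoperated = 0L,
         n_positive_no_histology = 0L, n_negative_no_histology = 0L,
         n_analyzable = 20L), class = "verified_counts"))
  expect_identical(perfect$metrics$sensitivity$estimate, 1)
  expect_identical(perfect$metrics$ppv$estimate, 1)
  expect_identical(perfect$metrics$accuracy$estimate, 1)
  expect_false(perfect$metrics$specificity$defined)

  empty <- make_cohort(cohort_row())
  expect_error(compute_performance(tally_verified(empty)),
               "no verified outcomes")
})

test_that("with a perfectly sensitive external test the adjustment can only raise NPV", {
  set.seed(31)
  for (i in 1:20) {
    v <- structure(list(
      tp = rpois(1, 30), tp_niftp = 0L, fp = rpois(1, 15),
      fn_operated = rpois(1, 2), tn_operated = rpois(1, 4),
      n_negative_unoperated = rpois(1, 100),
      n_positive_unoperated = 0L, n_positive_no_histology = 0L,
      n_negative_no_histology = 0L, n_analyzable = NA_integer_),
      class = "verified_counts")
    v$n_analyzable <- v$tp + v$fp + v$fn_operated + v$tn_operated +
      v$n_negative_unoperated
    if (v$tn_operated + v$fn_operated == 0) next
    naive_npv <- v$tn_operated / (v$tn_operated + v$fn_operated)
    adj <- adjust_counts(v, adjustment_config(1.0))
    adj_npv <- compute_performance(adj)$metrics$npv$estimate
    expect_gte(adj_npv, naive_npv)
  }
})
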