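test_that("flow counts reproduce the study flowchart and reconcile", {
  f <- flow_counts(replica_analysis())
  expect_identical(
    unclass(f)[c("n_analyzable", "n_test_negative", "n_test_positive",
                 "n_negative_operated", "n_negative_unoperated",
                 "n_positive_operated", "n_positive_unoperated",
                 "n_positive_operated_no_histology")],
    list(n_analyzable = 245L, n_test_negative = 157L, n_test_positive = 88L,
         n_negative_operated = 7L, n_negative_unoperated = 150L,
         n_positive_operated = 79L, n_positive_unoperated = 9L,
         n_positive_operated_no_histology = 1L))
  # every analyzable record is in exactly one terminal arm
  expect_identical(f$n_test_negative + f$n_test_positive, f$n_analyzable)
  expect_identical(f$n_negative_operated + f$n_negative_unoperated,
                   f$n_test_negative)
  expect_identical(f$n_positive_operated + f$n_positive_unoperated,
                   f$n_test_positive)
})

test_that("flow counts handle degenerate cohorts", {
  empty <- apply_exclusions(
    make_cohort(cohort_row(exclusion_flag = "collision_tumor",
                           surgery = TRUE, histology = "benign")))$cohort
  f <- flow_counts(empty)
  expect_true(all(unlist(unclass(f)) == 0L))

  allpos <- make_cohort(
    cohort_row("N1", test_result = "positive", surgery = TRUE,
               histology = "malignant"),
    cohort_row("N2", test_result = "positive", surgery = TRUE,
               histology = "benign"))
  f2 <- flow_counts(allpos)
  expect_identical(f2$n_positive_operated, 2L)
  expect_identical(f2$n_test_negative, 0L)
})

test_that("cohort summary reproduces the stratified characteristics table", {
  s <- summarize_cohort(replica_analysis())
  get <- function(var, lev) s$strata[s$strata$variable == var &
                                       s$strata$level == lev, ]
  age_young <- get("age", "20-54")
  expect_identical(c(age_young$n_negative, age_young$n_positive), c(81L, 58L))
  female <- get("sex", "female")
  expect_identical(c(female$n_negative, female$n_positive), c(127L, 78L))
  b4 <- get("bethesda", "IV")
  expect_identical(c(b4$n_negative, b4$n_positive), c(122L, 69L))
  surg <- get("surgery", "yes")
  expect_identical(c(surg$n_negative, surg$n_positive), c(7L, 79L))

  expect_equal(s$mean_age_years, 51.6)
  expect_equal(s$mean_nodule_size_cm, 1.2)
  fu <- s$followup_unoperated_negative
  expect_identical(fu$n, 150L)
  expect_equal(fu$mean_days, 706)
  expect_identical(c(fu$min_days, fu$max_days), c(10L, 1451L))

  p <- function(var) s$tests$p_value[s$tests$variable == var]
  expect_equal(round(p("age"), 2), 0.04)
  expect_lt(p("surgery"), 0.001)
  expect_gt(p("bethesda"), 0.9)

  # percentages within each column sum to 100 (+- rounding at 1 decimal)
  for (var in unique(s$strata$variable)) {
    sub <- s$strata[s$strata$variable == var, ]
    for (col in c("n_overall", "n_negative", "n_positive")) {
      den <- switch(col, n_overall = s$n, n_negative = s$n_negative,
                    n_positive = s$n_positive)
      pct <- round(100 * sub[[col]] / den, 1)
      expect_equal(sum(pct), 100, tolerance = 0.11)
    }
  }
})

test_that("cohort summary handles a single record", {
  s <- summarize_cohort(make_cohort(cohort_row(age_years = 30)))
  young <- s$strata[s$strata$variable == "age" & s$strata$level == "20-54", ]
  expect_identical(young$n_overall, 1L)
  expect_identical(sum(s$strata$n_overall[s$strata$variable == "age"]), 1L)
  expect_true(all(is.na(s$tests$p_value)))
})

test_that("histology tabulation reproduces the subtype table", {
  h <- tabulate_histology(replica_analysis())
  expect_identical(attr(h, "n_total"), 85L)
  fa_fp <- h$n[h$test_result == "positive" & h$truth == "benign" &
                 h$histology_subtype == "Follicular adenoma"]
  expect_identical(fa_fp, 21L)
  # grand total = operated with reports
  f <- flow_counts(replica_analysis())
  expect_identical(attr(h, "n_total"),
                   f$n_negative_operated + f$n_positive_operated -
                     f$n_positive_operated_no_histology)
})

test_that("histology tabulation edge cases", {
  none <- make_cohort(cohort_row())
  h <- tabulate_histology(none)
  expect_identical(nrow(h), 0L)
  expect_identical(attr(h, "n_total"), 0L)

  # one true positive per malignant subtype tallies one row each
  vocab <- histology_vocabulary()
  mal <- vocab$subtype[vocab$class == "malignant"]
  rows <- lapply(seq_along(mal), function(i)
    cohort_row(sprintf("N%d", i), test_result = "positive", surgery = TRUE,
               histology = ifelse(mal[i] == "NIFTP", "NIFTP", "malignant"),
               histology_subtype = mal[i]))
  h2 <- tabulate_histology(do.call(make_cohort, rows))
  expect_identical(nrow(h2), length(mal))
  expect_true(all(h2$n == 1L))
  expect_true(all(h2$truth == "malignant"))

  # out-of-vocabulary subtype is bucketed with a warning
  odd <- make_cohort(cohort_row(surgery = TRUE, histology = "benign",
                                histology_subtype = "cystic something"))
  expect_warning(h3 <- tabulate_histology(odd), "controlled vocabulary")
  expect_identical(h3$histology_subtype, "Other")

  # case/whitespace-insensitive matching
  sloppy <- make_cohort(cohort_row(surgery = TRUE, histology = "benign",
                                   histology_subtype = "  follicular   ADENOMA "))
  expect_identical(tabulate_histology(sloppy)$histology_subtype,
                   "Follicular adenoma")
})
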