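# Verified 2x2 tally, Bayes/Hall imputation of unverified test-negatives,
# and naive vs verification-adjusted diagnostic performance.
#
# The estimation problem: histopathology (the reference standard) exists only
# for operated nodules, and surgery is strongly test-result-dependent, so the
# operated-only ("naive") 2x2 is distorted by partial verification bias.
# Following Hall's Bayes-theorem device, the unoperated test-negative stratum
# is split into theoretical true-benign and missed-malignant counts using an
# externally established test sensitivity, and performance is recomputed on
# the augmented table. Only the negative arm is imputed: unoperated
# test-positives never enter a 2x2 cell (a deliberate asymmetry of the
# method).

#' Tally the verified 2x2 and unverified strata
#'
#' Assigns every record of the analysis cohort to exactly one stratum:
#' the four verified cells (operated with histology; truth via
#' [truth_label()], so NIFTP counts as a true positive), the unoperated arms,
#' and operated-without-report strata. `tp_niftp` records how many true
#' positives are NIFTP, which the clinical-utility accounting needs.
#'
#' @param cohort Post-exclusion `nodule_cohort`.
#'
#' @return A `verified_counts` list: `tp`, `tp_niftp`, `fp`, `fn_operated`,
#'   `tn_operated`, `n_negative_unoperated`, `n_positive_unoperated`,
#'   `n_positive_no_histology`, `n_negative_no_histology`, `n_analyzable`.
#'   The cells plus unverified strata always sum to `n_analyzable`.
#' @export
tally_verified <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  pos <- cohort$test_result == "positive"
  op <- cohort$surgery
  truth <- truth_label(cohort$histology)
  # operated test-negatives without a report stay outside every 2x2 cell in
  # a dedicated stratum (n_negative_no_histology), visible in the print log
  no_hist_neg <- sum(!pos & op & truth == "unknown")
  structure(list(
    tp = sum(pos & op & truth == "malignant"),
    tp_niftp = sum(pos & op & cohort$histology == "NIFTP"),
    fp = sum(pos & op & truth == "benign"),
    fn_operated = sum(!pos & op & truth == "malignant"),
    tn_operated = sum(!pos & op & truth == "benign"),
    n_negative_unoperated = sum(!pos & !op),
    n_positive_unoperated = sum(pos & !op),
    n_positive_no_histology = sum(pos & op & truth == "unknown"),
    n_negative_no_histology = no_hist_neg,
    n_analyzable = nrow(cohort)
  ), class = "verified_counts")
}

#' @export
print.verified_counts <- function(x, ...) {
  cat(sprintf("verified 2x2 (operated, histology available):\n"))
  cat(sprintf("  TP %d (of which NIFTP %d)  FP %d\n", x$tp, x$tp_niftp, x$fp))
  cat(sprintf("  FN %d  TN %d\n", x$fn_operated, x$tn_operated))
  cat(sprintf("unverified: %d unoperated negative, %d unoperated positive, %d operated without report\n",
              x$n_negative_unoperated, x$n_positive_unoperated,
              x$n_positive_no_histology + x$n_negative_no_histology))
  invisible(x)
}

#' Imputation configuration
#'
#' Parameters of the Bayes/Hall imputation: the externally established test
#' sensitivity applied to unoperated test-negative nodules (default 0.946,
#' the sensitivity reported by the classifier's original validation study)
#' and the integer rounding rule for the imputed missed-malignant count
#' (default nearest, half away from zero, which turns 150 x 0.054 = 8.1 into
#' 8 missed cancers; floor/ceiling are exposed for sensitivity analysis).
#'
#' @param external_sensitivity Fraction in (0, 1].
#' @param rounding One of `"nearest"`, `"floor"`, `"ceiling"`.
#' @return An `adjustment_config` list.
#' @export
adjustment_config <- function(external_sensitivity = 0.946,
                              rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(external_sensitivity) || length(external_sensitivity) != 1L ||
      external_sensitivity <= 0 || external_sensitivity > 1) {
    stop("`external_sensitivity` must be a single fraction in (0, 1]",
         call. = FALSE)
  }
  structure(list(external_sensitivity = external_sensitivity,
                 rounding = rounding),
            class = "adjustment_config")
}

#' Impute outcomes for unverified test-negative nodules
#'
#' Splits `n` unoperated test-negative nodules into theoretical true-benign
#' and missed-malignant counts by applying an external sensitivity:
#' `fn_imputed = round(n * (1 - external_sensitivity))` under the configured
#' rounding rule, `tn_imputed = n - fn_imputed`.
#'
#' @param n Number of unoperated test-negative nodules.
#' @param config An [adjustment_config()].
#'
#' @return A list with `tn_imputed` and `fn_imputed` (both non-negative,
#'   summing to `n`).
#'
#' @examples
#' impute_unverified_negatives(150, adjustment_config(0.946)) # 142 / 8
#' @export
impute_unverified_negatives <- function(n, config = adjustment_config()) {
  stopifnot(inherits(config, "adjustment_config"),
            length(n) == 1L, is.numeric(n), n >= 0, n == round(n))
  raw <- n * (1 - config$external_sensitivity)
  fn <- switch(config$rounding,
    nearest = floor(raw + 0.5),  # half away from zero (raw >= 0 here)
    floor = floor(raw),
    ceiling = ceiling(raw)
  )
  fn <- as.integer(min(max(fn, 0), n))
  list(tn_imputed = as.integer(n) - fn, fn_imputed = fn)
}

#' Build the verification-adjusted 2x2
#'
#' Copies the verified cells and adds the imputed split of the unoperated
#' test-negative stratum. Unoperated test-positives and operated nodules
#' without an accessible report never enter a 2x2 cell; they are carried
#' along for conservation accounting and the clinical-utility module.
#'
#' @param v A `verified_counts` from [tally_verified()].
#' @param config An [adjustment_config()].
#'
#' @return An `adjusted_counts` list: `tp`, `tp_niftp`, `fp`, `fn_observed`,
#'   `fn_imputed`, `tn_observed`, `tn_imputed`, plus pass-through strata
#'   (`n_positive_unoperated`, `n_positive_no_histology`,
#'   `n_negative_no_histology`, `n_analyzable`) and the `config` used.
#'   Derived totals: `fn_total = fn_observed + fn_imputed`,
#'   `tn_total = tn_observed + tn_imputed`.
#' @export
adjust_counts <- function(v, config = adjustment_config()) {
  stopifnot(inherits(v, "verified_counts"))
  imp <- impute_unverified_negatives(v$n_negative_unoperated, config)
  structure(list(
    tp = v$tp,
    tp_niftp = v$tp_niftp,
    fp = v$fp,
    fn_observed = v$fn_operated,
    fn_imputed = imp$fn_imputed,
    tn_observed = v$tn_operated,
    tn_imputed = imp$tn_imputed,
    n_positive_unoperated = v$n_positive_unoperated,
    n_positive_no_histology = v$n_positive_no_histology,
    n_negative_no_histology = v$n_negative_no_histology,
    n_analyzable = v$n_analyzable,
    config = config
  ), class = "adjusted_counts")
}

#' @export
print.adjusted_counts <- function(x, ...) {
  cat("verification-adjusted 2x2 (imputed cells marked *):\n")
  cat(sprintf("  TP %d           FP %d\n", x$tp, x$fp))
  cat(sprintf("  FN %d* + %d (%d)  TN %d* + %d (%d)\n",
              x$fn_imputed, x$fn_observed, x$fn_imputed + x$fn_observed,
              x$tn_imputed, x$tn_observed, x$tn_imputed + x$tn_observed))
  cat(sprintf("  external sensitivity %.3f, rounding %s\n",
              x$config$external_sensitivity, x$config$rounding))
  invisible(x)
}

#' Diagnostic performance with exact intervals
#'
#' Computes sensitivity, specificity, PPV, NPV, accuracy and disease
#' prevalence from a 2x2, each as a [proportion_ci()] with its own
#' Clopper-Pearson interval. Two modes:
#'
#' * `verified_counts` input -> naive mode, using only the operated cells
#'   (`tp`, `fp`, `fn_operated`, `tn_operated`): the partial-verification-
#'   biased estimate.
#' * `adjusted_counts` input -> adjusted mode, using
#'   `fn_total = fn_observed + fn_imputed` and
#'   `tn_total = tn_observed + tn_imputed`.
#'
#' Caveat, printed with every adjusted report: imputed cells are theoretical
#' counts, not binomial observations, so the exact intervals on adjusted
#' metrics mirror the usual reporting convention rather than a sampling
#' guarantee.
#'
#' @param x A `verified_counts` or `adjusted_counts`.
#' @param conf_level Confidence level for all intervals.
#' @param ... Unused.
#'
#' @return A `performance_report`: list with `mode`, `cells` (the 2x2 used),
#'   and `metrics`, a named list of `proportion` objects (`sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `prevalence`; a metric with a
#'   zero denominator is undefined, not 0).
#'
#' @examples
#' v <- structure(list(tp = 49, tp_niftp = 2, fp = 29, fn_operated = 2,
#'                     tn_operated = 5, n_negative_unoperated = 150,
#'                     n_positive_unoperated = 9, n_positive_no_histology = 1,
#'                     n_negative_no_histology = 0, n_analyzable = 245),
#'                class = "verified_counts")
#' compute_performance(adjust_counts(v))
#' @export
compute_performance <- function(x, conf_level = 0.95, ...) {
  UseMethod("compute_performance")
}

#' @rdname compute_performance
#' @export
compute_performance.verified_counts <- function(x, conf_level = 0.95, ...) {
  performance_from_cells(tp = x$tp, fp = x$fp, fn = x$fn_operated,
                         tn = x$tn_operated, mode = "naive",
                         conf_level = conf_level)
}

#' @rdname compute_performance
#' @export
compute_performance.adjusted_counts <- function(x, conf_level = 0.95, ...) {
  performance_from_cells(tp = x$tp, fp = x$fp,
                         fn = x$fn_observed + x$fn_imputed,
                         tn = x$tn_observed + x$tn_imputed,
                         mode = "adjusted", conf_level = conf_level)
}

performance_from_cells <- function(tp, fp, fn, tn, mode, conf_level) {
  n <- tp + fp + fn + tn
  if (n == 0) {
    stop("no verified outcomes: all 2x2 cells are zero", call. = FALSE)
  }
  metric <- function(num, den) {
    if (den == 0) proportion_ci(0, 0, conf_level)
    else proportion_ci(num, den, conf_level)
  }
  structure(list(
    mode = mode,
    conf_level = conf_level,
    cells = list(tp = tp, fp = fp, fn = fn, tn = tn, n = n),
    metrics = list(
      sensitivity = metric(tp, tp + fn),
      specificity = metric(tn, tn + fp),
      ppv = metric(tp, tp + fp),
      npv = metric(tn, tn + fn),
      accuracy = metric(tp + tn, n),
      prevalence = metric(tp + fn, n)
    )
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("diagnostic performance (%s mode; %g%% Clopper-Pearson CIs)\n",
              x$mode, 100 * x$conf_level))
  cat(sprintf("  2x2: TP %d  FP %d  FN %d  TN %d  (N = %d)\n",
              x$cells$tp, x$cells$fp, x$cells$fn, x$cells$tn, x$cells$n))
  labels <- c(sensitivity = "Sensitivity", specificity = "Specificity",
              ppv = "PPV", npv = "NPV", accuracy = "Accuracy",
              prevalence = "Disease prevalence")
  for (m in names(labels)) {
    p <- x$metrics[[m]]
    if (!p$defined) {
      cat(sprintf("  %-18s undefined (zero denominator)\n", labels[[m]]))
    } else {
      cat(sprintf("  %-18s %s%% (%s-%s)  [%d/%d]\n", labels[[m]],
                  fmt_pct(p$estimate), fmt_pct(p$conf_low),
                  fmt_pct(p$conf_high), p$numerator, p$denominator))
    }
  }
  if (x$mode == "adjusted") {
    cat("  note: imputed cells are theoretical counts, not binomial observations;\n")
    cat("  intervals on adjusted metrics follow the usual reporting convention.\n")
  }
  invisible(x)
}
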