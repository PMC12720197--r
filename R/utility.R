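# Clinical utility: decision-support (concordance) rates and the two
# counterfactual surgery-avoidance statistics.
#
# The counterfactual: without molecular testing, every analyzable nodule
# would have gone to diagnostic surgery except those test-positives whose
# patients declined or deferred surgery anyway (they are removed from the
# denominator, mirroring the study's accounting; the all-nodules denominator
# is available behind `counterfactual = "all"` and clearly labelled
# non-default).

#' Decision-support (concordance) rates
#'
#' Fraction of nodules whose clinical management matched the test result:
#' surveillance (no surgery) for test-negatives, surgery for test-positives.
#' An operated test-positive without an accessible histopathology report
#' still counts as supported -- it was operated on a positive test.
#'
#' @param f A [flow_counts()] object with `n_analyzable > 0`.
#' @param conf_level Confidence level for the Clopper-Pearson intervals.
#'
#' @return A list of three [proportion_ci()] objects:
#'   `support_when_negative` (unoperated negatives / all negatives),
#'   `support_when_positive` (operated positives / all positives),
#'   `overall_concordance` (their numerator sum / all analyzable nodules).
#'   A zero arm yields an undefined proportion (not applicable), never 0.
#' @export
decision_support <- function(f, conf_level = 0.95) {
  stopifnot(inherits(f, "flow_counts"))
  if (f$n_analyzable == 0) {
    stop("empty analysis cohort: no decision-support rates", call. = FALSE)
  }
  list(
    support_when_negative =
      proportion_ci(f$n_negative_unoperated, f$n_test_negative, conf_level),
    support_when_positive =
      proportion_ci(f$n_positive_operated, f$n_test_positive, conf_level),
    overall_concordance =
      proportion_ci(f$n_negative_unoperated + f$n_positive_operated,
                    f$n_analyzable, conf_level)
  )
}

#' Surgeries avoided under the counterfactual
#'
#' Fraction of counterfactual surgeries avoided thanks to the test: the
#' numerator is the unoperated test-negative nodules; the denominator is all
#' analyzable nodules minus the unoperated test-positives (default), i.e.
#' everyone assumed to undergo thyroidectomy had no molecular test existed.
#'
#' @param f A [flow_counts()] object.
#' @param counterfactual `"exclude_unoperated_positives"` (default, the
#'   study's accounting) or `"all"` (denominator = all analyzable nodules;
#'   a non-default variant for sensitivity analysis).
#' @param conf_level Confidence level.
#'
#' @return A [proportion_ci()].
#' @export
surgeries_avoided <- function(f,
                              counterfactual = c("exclude_unoperated_positives",
                                                 "all"),
                              conf_level = 0.95) {
  stopifnot(inherits(f, "flow_counts"))
  counterfactual <- match.arg(counterfactual)
  den <- switch(counterfactual,
    exclude_unoperated_positives = f$n_analyzable - f$n_positive_unoperated,
    all = f$n_analyzable
  )
  if (den <= 0) {
    stop("non-positive counterfactual denominator", call. = FALSE)
  }
  proportion_ci(f$n_negative_unoperated, den, conf_level)
}

#' Potentially unnecessary surgeries avoided
#'
#' Among the nodules the adjusted table regards as benign
#' (`tn_imputed + tn_observed + fp`), the fraction whose surgery was avoided.
#' Resections counted as "potentially unnecessary" are the operated benign
#' nodules (`tn_observed + fp`) plus, by default, the NIFTP resections:
#' NIFTP is an indolent neoplasm counted as malignant only for
#' test-performance purposes, so its surgery belongs in the
#' potentially-unnecessary tally (study accounting: 29 FP + 5 TN + 2 NIFTP =
#' 36 operated out of 176, hence 140/176 avoided).
#'
#' @param a An [adjust_counts()] result.
#' @param conf_level Confidence level.
#' @param count_niftp Count NIFTP resections among the potentially
#'   unnecessary operations (default `TRUE`, the study's accounting).
#'
#' @return A [proportion_ci()] over the benign pool; undefined if the pool
#'   is empty.
#' @export
potentially_unnecessary_avoided <- function(a, conf_level = 0.95,
                                            count_niftp = TRUE) {
  stopifnot(inherits(a, "adjusted_counts"))
  benign_total <- a$tn_imputed + a$tn_observed + a$fp
  if (benign_total == 0) {
    return(proportion_ci(0, 0, conf_level))
  }
  operated <- a$tn_observed + a$fp + if (count_niftp) a$tp_niftp else 0L
  avoided <- benign_total - operated
  if (avoided < 0) {
    warning("operated potentially-unnecessary count exceeds the benign pool; clamping at 0",
            call. = FALSE)
    avoided <- 0L
  }
  proportion_ci(avoided, benign_total, conf_level)
}

#' Full clinical-utility report
#'
#' Bundles the concordance rates and both surgery-avoidance statistics with
#' an explicit record of every counterfactual assumption used.
#'
#' @param f A [flow_counts()] object.
#' @param a An [adjust_counts()] result (for the potentially-unnecessary
#'   accounting).
#' @param counterfactual Passed to [surgeries_avoided()].
#' @param count_niftp Passed to [potentially_unnecessary_avoided()].
#' @param conf_level Confidence level.
#'
#' @return A `utility_report` list: the five proportions plus `assumptions`.
#' @export
clinical_utility <- function(f, a,
                             counterfactual = "exclude_unoperated_positives",
                             count_niftp = TRUE, conf_level = 0.95) {
  ds <- decision_support(f, conf_level)
  structure(list(
    support_when_negative = ds$support_when_negative,
    support_when_positive = ds$support_when_positive,
    overall_concordance = ds$overall_concordance,
    surgeries_avoided = surgeries_avoided(f, counterfactual, conf_level),
    potentially_unnecessary_avoided =
      potentially_unnecessary_avoided(a, conf_level, count_niftp),
    assumptions = list(
      counterfactual_denominator = counterfactual,
      niftp_resections_potentially_unnecessary = count_niftp,
      external_sensitivity = a$config$external_sensitivity,
      imputation_rounding = a$config$rounding,
      note = paste("utility rates are treated as binomial proportions for",
                   "interval purposes; imputed cells are theoretical counts")
    )
  ), class = "utility_report")
}

#' @export
print.utility_report <- function(x, ...) {
  row <- function(label, p) {
    cat(sprintf("  %-34s %s", label, format(p)))
    if (p$defined) cat(sprintf("  [%d/%d]", p$numerator, p$denominator))
    cat("\n")
  }
  cat("clinical utility\n")
  row("decision support, test-negative", x$support_when_negative)
  row("decision support, test-positive", x$support_when_positive)
  row("overall concordance", x$overall_concordance)
  row("surgeries avoided", x$surgeries_avoided)
  row("potentially unnecessary avoided", x$potentially_unnecessary_avoided)
  cat(sprintf("  counterfactual: %s; NIFTP resections potentially unnecessary: %s\n",
              x$assumptions$counterfactual_denominator,
              x$assumptions$niftp_resections_potentially_unnecessary))
  invisible(x)
}
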