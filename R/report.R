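# End-to-end pipeline: ingest -> exclusions -> descriptives -> performance
# (naive + adjusted) -> clinical utility, with JSON and markdown renderings.
# Every number in the markdown tables is present, at full precision, in the
# JSON bundle.

#' Run the full analysis pipeline
#'
#' Composes the whole package on one cohort: validation, exclusions, flow
#' counts, stratified characteristics, histopathology tabulation, naive and
#' verification-adjusted performance (always both, so the effect of the
#' adjustment is visible side by side), and clinical utility, together with
#' an explicit assumptions block.
#'
#' @param input Path to a cohort CSV, or a `nodule_cohort`.
#' @param output_dir If non-`NULL`, writes `report.json` and `report.md`
#'   there (created if needed).
#' @param conf_level Confidence level for all intervals.
#' @param external_sensitivity,rounding Imputation settings; see
#'   [adjustment_config()].
#' @param counterfactual Passed to [surgeries_avoided()].
#' @param count_niftp Passed to [potentially_unnecessary_avoided()].
#'
#' @return An `analysis_bundle` list: `provenance`, `exclusions`, `flow`,
#'   `summary`, `histology`, `performance_naive`, `performance_adjusted`,
#'   `utility`, `assumptions`.
#'
#' @examples
#' csv <- system.file("extdata", "study_cohort_synthetic.csv",
#'                    package = "thyverify")
#' bundle <- run_analysis(csv)
#' bundle$performance_adjusted
#' @export
run_analysis <- function(input, output_dir = NULL, conf_level = 0.95,
                         external_sensitivity = 0.946, rounding = "nearest",
                         counterfactual = "exclude_unoperated_positives",
                         count_niftp = TRUE) {
  cohort <- if (inherits(input, "nodule_cohort")) input else read_cohort(input)
  excl <- apply_exclusions(cohort)
  if (excl$log$n_analyzable == 0) {
    stop("no analyzable nodules after exclusions", call. = FALSE)
  }
  analysis <- excl$cohort
  cfg <- adjustment_config(external_sensitivity, rounding)
  flow <- flow_counts(analysis)
  v <- tally_verified(analysis)
  adj <- adjust_counts(v, cfg)
  bundle <- structure(list(
    provenance = attr(cohort, "provenance"),
    exclusions = excl$log,
    flow = flow,
    call_rates = list(
      benign = proportion_ci(flow$n_test_negative, flow$n_analyzable,
                             conf_level),
      malignant = proportion_ci(flow$n_test_positive, flow$n_analyzable,
                                conf_level)
    ),
    summary = summarize_cohort(analysis),
    histology = tabulate_histology(analysis),
    verified = v,
    adjusted = adj,
    performance_naive = compute_performance(v, conf_level),
    performance_adjusted = compute_performance(adj, conf_level),
    utility = clinical_utility(flow, adj, counterfactual, count_niftp,
                               conf_level),
    assumptions = list(
      conf_level = conf_level,
      external_sensitivity = external_sensitivity,
      imputation_rounding = rounding,
      counterfactual_denominator = counterfactual,
      niftp_resections_potentially_unnecessary = count_niftp,
      truth_rule = "NIFTP counted as malignant; positive tests on NIFTP are true positives",
      interval_method = "Clopper-Pearson exact",
      caveat = paste("imputed cells are theoretical counts, not binomial",
                     "observations; intervals on adjusted metrics follow the",
                     "usual reporting convention")
    )
  ), class = "analysis_bundle")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_json(bundle), file.path(output_dir, "report.json"))
    writeLines(report_markdown(bundle), file.path(output_dir, "report.md"))
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
    x
  } else {
    unname(unclass(x))
  }
}

#' Serialise an analysis bundle to JSON
#'
#' Full-precision fractions and raw integer cells; the markdown rendering is
#' derived from the same bundle, so the two carry the same numbers.
#'
#' @param bundle An `analysis_bundle`.
#' @return A JSON string.
#' @export
report_json <- function(bundle) {
  x <- unclass(bundle)
  x$histology <- tibble::as_tibble(bundle$histology)
  x$summary$strata <- tibble::as_tibble(bundle$summary$strata)
  x$summary$tests <- tibble::as_tibble(bundle$summary$tests)
  keep_df <- c("histology")
  out <- lapply(names(x), function(nm) {
    if (nm %in% keep_df || is.data.frame(x[[nm]])) x[[nm]]
    else strip_classes(x[[nm]])
  })
  names(out) <- names(x)
  out$summary$strata <- x$summary$strata
  out$summary$tests <- x$summary$tests
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", na = "null"))
}

md_table <- function(header, rows) {
  fmt_row <- function(r) paste0("| ", paste(r, collapse = " | "), " |")
  c(fmt_row(header),
    fmt_row(rep("---", length(header))),
    vapply(rows, fmt_row, character(1)))
}

prop_cells <- function(p) {
  if (!p$defined) return(c("NA", "NA", "NA"))
  c(sprintf("%d/%d", p$numerator, p$denominator),
    fmt_pct(p$estimate),
    sprintf("%s-%s", fmt_pct(p$conf_low), fmt_pct(p$conf_high)))
}

#' Render an analysis bundle as markdown
#'
#' Human-readable counterpart of [report_json()]: percentages half-up at one
#' decimal with exact intervals in parentheses, observed/imputed cell
#' provenance marked with `*`.
#'
#' @param bundle An `analysis_bundle`.
#' @return A character vector of markdown lines.
#' @export
report_markdown <- function(bundle) {
  f <- bundle$flow
  s <- bundle$summary
  a <- bundle$adjusted
  u <- bundle$utility
  lines <- c(
    sprintf("# Classifier performance report (%s)", bundle$provenance),
    "",
    "## Cohort flow",
    "",
    sprintf("- input records: %d; excluded: %s; analyzable: %d",
            bundle$exclusions$n_input,
            paste(sprintf("%s %d", names(bundle$exclusions$n_excluded_by_reason),
                          bundle$exclusions$n_excluded_by_reason),
                  collapse = ", "),
            bundle$exclusions$n_analyzable),
    sprintf("- test-negative %d (benign call rate %s%%): %d operated, %d unoperated",
            f$n_test_negative, fmt_pct(bundle$call_rates$benign$estimate),
            f$n_negative_operated, f$n_negative_unoperated),
    sprintf("- test-positive %d (malignant call rate %s%%): %d operated (%d without report), %d unoperated",
            f$n_test_positive, fmt_pct(bundle$call_rates$malignant$estimate),
            f$n_positive_operated, f$n_positive_operated_no_histology,
            f$n_positive_unoperated),
    "",
    "## Cohort characteristics",
    ""
  )
  strata_rows <- lapply(seq_len(nrow(s$strata)), function(i) {
    r <- s$strata[i, ]
    p <- s$tests$p_value[s$tests$variable == r$variable]
    c(r$variable, r$level,
      sprintf("%d (%s)", r$n_overall, fmt_pct(r$n_overall / max(s$n, 1))),
      sprintf("%d (%s)", r$n_negative,
              fmt_pct(r$n_negative / max(s$n_negative, 1))),
      sprintf("%d (%s)", r$n_positive,
              fmt_pct(r$n_positive / max(s$n_positive, 1))),
      fmt_p(p))
  })
  lines <- c(lines,
    md_table(c("variable", "level", "overall n (%)", "negative n (%)",
               "positive n (%)", "p"), strata_rows),
    "",
    sprintf("mean age %.1f y; mean nodule size %.1f cm", s$mean_age_years,
            s$mean_nodule_size_cm))
  fu <- s$followup_unoperated_negative
  if (fu$n > 0) {
    lines <- c(lines,
      sprintf("follow-up of unoperated test-negatives (n=%d): mean %.0f days, range %d-%d",
              fu$n, fu$mean_days, fu$min_days, fu$max_days))
  }
  h <- tibble::as_tibble(bundle$histology)
  if (nrow(h) > 0) {
    lines <- c(lines, "", "## Histopathology of operated nodules", "",
      md_table(c("test result", "truth", "subtype", "n"),
               lapply(seq_len(nrow(h)), function(i)
                 c(h$test_result[i], h$truth[i], h$histology_subtype[i],
                   h$n[i]))),
      sprintf("total reports: %d", attr(bundle$histology, "n_total")))
  }
  lines <- c(lines, "", "## Adjusted 2x2 (imputed cells marked *)", "",
    md_table(c("", "test positive", "test negative"),
             list(c("malignant", sprintf("%d", a$tp),
                    sprintf("%d* + %d (%d)", a$fn_imputed, a$fn_observed,
                            a$fn_imputed + a$fn_observed)),
                  c("benign", sprintf("%d", a$fp),
                    sprintf("%d* + %d (%d)", a$tn_imputed, a$tn_observed,
                            a$tn_imputed + a$tn_observed)))),
    "")
  perf_rows <- function(report) {
    labels <- c(sensitivity = "Sensitivity", specificity = "Specificity",
                ppv = "PPV", npv = "NPV", accuracy = "Accuracy",
                prevalence = "Disease prevalence")
    lapply(names(labels), function(m)
      c(labels[[m]], prop_cells(report$metrics[[m]])))
  }
  lines <- c(lines,
    "## Diagnostic performance",
    "",
    "### Adjusted (Bayes-imputed unoperated test-negatives)",
    "",
    md_table(c("metric", "cells", "%", sprintf("%g%% CI",
               100 * bundle$performance_adjusted$conf_level)),
             perf_rows(bundle$performance_adjusted)),
    "",
    "### Naive (operated nodules only; partial-verification biased)",
    "",
    md_table(c("metric", "cells", "%", sprintf("%g%% CI",
               100 * bundle$performance_naive$conf_level)),
             perf_rows(bundle$performance_naive)),
    "",
    "## Clinical utility",
    "",
    md_table(c("measure", "cells", "%", "CI"),
             list(c("decision support, test-negative",
                    prop_cells(u$support_when_negative)),
                  c("decision support, test-positive",
                    prop_cells(u$support_when_positive)),
                  c("overall concordance", prop_cells(u$overall_concordance)),
                  c("surgeries avoided", prop_cells(u$surgeries_avoided)),
                  c("potentially unnecessary avoided",
                    prop_cells(u$potentially_unnecessary_avoided)))),
    "",
    "## Assumptions",
    "",
    sprintf("- external sensitivity %.3f, rounding %s",
            bundle$assumptions$external_sensitivity,
            bundle$assumptions$imputation_rounding),
    sprintf("- counterfactual denominator: %s",
            bundle$assumptions$counterfactual_denominator),
    sprintf("- NIFTP resections counted potentially unnecessary: %s",
            bundle$assumptions$niftp_resections_potentially_unnecessary),
    sprintf("- %s", bundle$assumptions$truth_rule),
    sprintf("- %s", bundle$assumptions$caveat)
  )
  lines
}

#' Run the simulation pipeline
#'
#' Simulates a cohort (optionally from a JSON parameter file), writes it as a
#' standard cohort CSV, and optionally runs a [bias_experiment()].
#'
#' @param params A [sim_params()] object or path to a JSON config (see
#'   [sim_params_from_file()]).
#' @param output_dir If non-`NULL`, writes `cohort.csv` (and `bias.json` when
#'   `bias_replicates > 0`) there. Outputs are deterministic given the seed.
#' @param bias_replicates Number of bias-experiment replicates (0 = skip).
#' @param external_sensitivity Passed to [bias_experiment()]; defaults to the
#'   generative sensitivity.
#'
#' @return A list with `cohort` and (possibly `NULL`) `bias`.
#' @export
run_simulation <- function(params = sim_params(), output_dir = NULL,
                           bias_replicates = 0,
                           external_sensitivity = NULL) {
  if (is.character(params)) params <- sim_params_from_file(params)
  stopifnot(inherits(params, "sim_params"))
  cohort <- simulate_cohort(params)
  bias <- NULL
  if (bias_replicates > 0) {
    if (is.null(external_sensitivity)) {
      external_sensitivity <- params$test_sensitivity
    }
    bias <- bias_experiment(params, bias_replicates, external_sensitivity)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    if (!is.null(bias)) {
      writeLines(as.character(jsonlite::toJSON(
        list(summary = bias$summary, truth = as.list(bias$truth),
             params = unclass(bias$params),
             n_replicates = bias$n_replicates),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")),
        file.path(output_dir, "bias.json"))
    }
  }
  list(cohort = cohort, bias = bias)
}
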