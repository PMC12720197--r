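# Descriptive layer: flow counts (study flowchart), stratified cohort
# characteristics, and the histopathology subtype tabulation.

#' Flow counts for an analysis cohort
#'
#' Tallies the terminal arms of the study flow: test result, then surgery
#' status, then (for operated test-positives) availability of the
#' histopathology report. Every analyzable record lands in exactly one
#' terminal arm.
#'
#' @param cohort Post-exclusion `nodule_cohort`.
#'
#' @return A `flow_counts` list: `n_analyzable`, `n_test_negative`,
#'   `n_test_positive`, `n_negative_operated`, `n_negative_unoperated`,
#'   `n_positive_operated`, `n_positive_unoperated`,
#'   `n_positive_operated_no_histology`. An empty cohort yields all zeros
#'   (call rates are then undefined and reported as not applicable).
#' @export
flow_counts <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  neg <- cohort$test_result == "negative"
  pos <- !neg
  op <- cohort$surgery
  structure(list(
    n_analyzable = nrow(cohort),
    n_test_negative = sum(neg),
    n_test_positive = sum(pos),
    n_negative_operated = sum(neg & op),
    n_negative_unoperated = sum(neg & !op),
    n_positive_operated = sum(pos & op),
    n_positive_unoperated = sum(pos & !op),
    n_positive_operated_no_histology =
      sum(pos & op & cohort$histology == "unavailable")
  ), class = "flow_counts")
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(sprintf("analyzable nodules: %d\n", x$n_analyzable))
  cat(sprintf("  test-negative: %d (operated %d, unoperated %d)\n",
              x$n_test_negative, x$n_negative_operated,
              x$n_negative_unoperated))
  cat(sprintf("  test-positive: %d (operated %d [%d without histology], unoperated %d)\n",
              x$n_test_positive, x$n_positive_operated,
              x$n_positive_operated_no_histology, x$n_positive_unoperated))
  invisible(x)
}

#' Stratified cohort characteristics
#'
#' Table-1 style summary: counts by test result stratified by age group
#' (dichotomised at `age_cut`, default 20-54 vs >54), sex, Bethesda class and
#' surgery status, with an association p-value per stratifier
#' (continuity-corrected chi-square, or Fisher's exact test when an expected
#' cell is below 5), plus mean age, mean nodule size and follow-up statistics
#' for unoperated test-negative nodules.
#'
#' Percentages are within test-result columns, rendered half-up at 1 decimal
#' by the print method; the object keeps full precision.
#'
#' @param cohort Post-exclusion `nodule_cohort`.
#' @param age_cut Upper bound of the younger age group, in years.
#'
#' @return A `cohort_summary` list with elements `n`, `strata` (tibble:
#'   `variable`, `level`, `n_overall`, `n_negative`, `n_positive`),
#'   `tests` (tibble: `variable`, `method`, `p_value`), `mean_age_years`,
#'   `mean_nodule_size_cm`, and `followup_unoperated_negative`
#'   (`n`, `mean_days`, `min_days`, `max_days`).
#' @export
summarize_cohort <- function(cohort, age_cut = 54) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  df <- tibble::as_tibble(cohort)
  df$age_group <- ifelse(df$age_years <= age_cut,
                         sprintf("20-%d", age_cut), sprintf(">%d", age_cut))
  strat_vars <- list(
    age = list(col = "age_group",
               levels = c(sprintf("20-%d", age_cut), sprintf(">%d", age_cut))),
    sex = list(col = "sex", levels = SEX_LEVELS),
    bethesda = list(col = "bethesda", levels = BETHESDA_LEVELS),
    surgery = list(col = "surgery", levels = c(FALSE, TRUE),
                   labels = c("no", "yes"))
  )

  strata <- list()
  tests <- list()
  for (v in names(strat_vars)) {
    sv <- strat_vars[[v]]
    vals <- df[[sv$col]]
    labels <- if (!is.null(sv$labels)) sv$labels else as.character(sv$levels)
    counts <- t(vapply(seq_along(sv$levels), function(i) {
      in_level <- vals == sv$levels[[i]]
      c(overall = sum(in_level),
        negative = sum(in_level & df$test_result == "negative"),
        positive = sum(in_level & df$test_result == "positive"))
    }, numeric(3)))
    strata[[v]] <- tibble::tibble(
      variable = v, level = labels,
      n_overall = as.integer(counts[, "overall"]),
      n_negative = as.integer(counts[, "negative"]),
      n_positive = as.integer(counts[, "positive"])
    )
    tab <- counts[, c("negative", "positive"), drop = FALSE]
    tests[[v]] <- if (nrow(df) > 0 && sum(tab) > 0 &&
                        !any(colSums(tab) == 0) && !any(rowSums(tab) == 0)) {
      at <- assoc_test_2x2(tab)
      tibble::tibble(variable = v, method = at$method, p_value = at$p_value)
    } else {
      tibble::tibble(variable = v, method = NA_character_,
                     p_value = NA_real_)
    }
  }

  fu <- df[df$test_result == "negative" & !df$surgery, ]
  fud <- fu$followup_days[!is.na(fu$followup_days)]
  structure(list(
    n = nrow(df),
    n_negative = sum(df$test_result == "negative"),
    n_positive = sum(df$test_result == "positive"),
    strata = dplyr::bind_rows(strata),
    tests = dplyr::bind_rows(tests),
    mean_age_years = mean(df$age_years),
    mean_nodule_size_cm = mean(df$nodule_size_cm, na.rm = TRUE),
    followup_unoperated_negative = list(
      n = length(fud),
      mean_days = if (length(fud)) mean(fud) else NA_real_,
      min_days = if (length(fud)) min(fud) else NA_integer_,
      max_days = if (length(fud)) max(fud) else NA_integer_
    ),
    age_cut = age_cut
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("analyzable nodules: %d (%d test-negative, %d test-positive)\n",
              x$n, x$n_negative, x$n_positive))
  pct <- function(n, d) if (d > 0) sprintf("%s", fmt_pct(n / d)) else "NA"
  for (v in unique(x$strata$variable)) {
    p <- x$tests$p_value[x$tests$variable == v]
    cat(sprintf("%s (p = %s)\n", v, fmt_p(p)))
    s <- x$strata[x$strata$variable == v, ]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-8s %3d (%s)  neg %3d (%s)  pos %3d (%s)\n",
                  s$level[i],
                  s$n_overall[i], pct(s$n_overall[i], x$n),
                  s$n_negative[i], pct(s$n_negative[i], x$n_negative),
                  s$n_positive[i], pct(s$n_positive[i], x$n_positive)))
    }
  }
  cat(sprintf("mean age: %.1f y; mean nodule size: %.1f cm\n",
              x$mean_age_years, x$mean_nodule_size_cm))
  fu <- x$followup_unoperated_negative
  if (fu$n > 0) {
    cat(sprintf("follow-up (unoperated test-negative, n=%d): mean %.0f days, range %d-%d\n",
                fu$n, fu$mean_days, fu$min_days, fu$max_days))
  }
  invisible(x)
}

#' Controlled vocabulary of histopathology subtypes
#'
#' The recognised post-surgical diagnosis labels and their benign/malignant
#' class (NIFTP counts as malignant for test performance). Matching in
#' [tabulate_histology()] is case-insensitive after whitespace normalisation.
#'
#' @return A tibble with `subtype` and `class`.
#' @export
histology_vocabulary <- function() {
  tibble::tibble(
    subtype = c(
      "Follicular adenoma",
      "Oncocytic adenoma of the thyroid",
      "Thyroid follicular nodular disease",
      "Thyroiditis",
      "Papillary thyroid micro/carcinoma variant follicular",
      "Papillary thyroid micro/carcinoma classic",
      "Papillary thyroid micro/carcinoma subtype solid",
      "Papillary thyroid microcarcinoma subtype oncocytic",
      "Oncocytic microcarcinoma of the thyroid",
      "Follicular thyroid carcinoma minimally invasive",
      "NIFTP"
    ),
    class = c(rep("benign", 4), rep("malignant", 7))
  )
}

normalize_subtype <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Histopathology subtype tabulation
#'
#' Table-2 style tally: counts of each post-surgical subtype by test result
#' and truth class. Only operated records with an available histopathology
#' report contribute; the grand total therefore equals the number of operated
#' nodules minus those without an accessible report.
#'
#' Subtype strings are matched case-insensitively (whitespace normalised)
#' against [histology_vocabulary()]; values outside the vocabulary are
#' bucketed as `"Other"` with a warning, and records with available histology
#' but no subtype string as `"Unspecified"`.
#'
#' @param cohort Post-exclusion `nodule_cohort`.
#'
#' @return A tibble with `test_result`, `truth`, `histology_subtype`, `n`,
#'   carrying the grand total as attribute `n_total`.
#' @export
tabulate_histology <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  df <- tibble::as_tibble(cohort)
  df <- df[df$surgery & df$histology != "unavailable", ]
  if (nrow(df) == 0) {
    out <- tibble::tibble(test_result = character(), truth = character(),
                          histology_subtype = character(), n = integer())
    attr(out, "n_total") <- 0L
    return(out)
  }
  vocab <- histology_vocabulary()
  idx <- match(normalize_subtype(df$histology_subtype),
               normalize_subtype(vocab$subtype))
  subtype <- vocab$subtype[idx]
  unknown <- !is.na(df$histology_subtype) & is.na(idx)
  if (any(unknown)) {
    warning(sprintf("histology_subtype outside controlled vocabulary bucketed as 'Other': %s",
                    paste(unique(df$histology_subtype[unknown]), collapse = ", ")),
            call. = FALSE)
    subtype[unknown] <- "Other"
  }
  subtype[is.na(df$histology_subtype)] <- "Unspecified"
  df$histology_subtype <- subtype
  df$truth <- truth_label(df$histology)
  out <- dplyr::count(df, .data$test_result, .data$truth,
                      .data$histology_subtype, name = "n")
  attr(out, "n_total") <- sum(out$n)
  out
}
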