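# Nodule-level cohort data model: construction, CSV ingestion/writing,
# validation, exclusion handling and truth labelling.
#
# One row = one tested nodule. Analyses are nodule-level throughout; patients
# may contribute several nodules (patient_id repeats, nodule_id never does).

SEX_LEVELS <- c("female", "male")
BETHESDA_LEVELS <- c("III", "IV")
TEST_LEVELS <- c("negative", "positive")
HISTOLOGY_LEVELS <- c("benign", "malignant", "NIFTP", "unavailable")
EXCLUSION_LEVELS <- c("none", "collision_tumor", "unmatched_nodule")

REQUIRED_COLUMNS <- c("patient_id", "nodule_id", "age_years", "sex",
                      "bethesda", "test_result", "surgery", "histology",
                      "exclusion_flag")
OPTIONAL_COLUMNS <- c("nodule_size_cm", "histology_subtype", "followup_days")
COHORT_COLUMNS <- c("patient_id", "nodule_id", "age_years", "sex", "bethesda",
                    "nodule_size_cm", "test_result", "surgery", "histology",
                    "histology_subtype", "followup_days", "exclusion_flag")

# Case-insensitive mapping onto a canonical level set; returns canonical
# values with NA for inputs outside the set.
match_level <- function(x, levels) {
  levels[match(tolower(trimws(x)), tolower(levels))]
}

#' Construct a validated nodule cohort
#'
#' Coerces a data frame with the cohort schema to a validated `nodule_cohort`
#' tibble. Enumerated columns are matched case-insensitively; all record
#' invariants are enforced (see Details).
#'
#' @details Invariants checked per record:
#' * `nodule_id` unique; `patient_id` may repeat (multi-nodule patients);
#' * `age_years >= 18` (adult study population);
#' * `surgery = FALSE` implies `histology = "unavailable"` (histopathology
#'   exists only for operated nodules);
#' * `histology = "NIFTP"` implies `surgery = TRUE` (NIFTP is a strictly
#'   post-surgical diagnosis);
#' * `nodule_size_cm` positive when present; `followup_days` non-negative.
#'
#' @param x A data frame with columns `patient_id`, `nodule_id`, `age_years`,
#'   `sex`, `bethesda`, `test_result`, `surgery`, `histology`,
#'   `exclusion_flag`, and optionally `nodule_size_cm`, `histology_subtype`,
#'   `followup_days`.
#' @param provenance Free-text source label stored as an attribute.
#'
#' @return A `nodule_cohort` tibble with the canonical column order.
#' @export
as_nodule_cohort <- function(x, provenance = "unspecified") {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(OPTIONAL_COLUMNS, names(x))) {
    x[[col]] <- switch(col,
      nodule_size_cm = NA_real_,
      histology_subtype = NA_character_,
      followup_days = NA_integer_
    )
  }

  out <- tibble::tibble(
    patient_id = as.character(x$patient_id),
    nodule_id = as.character(x$nodule_id),
    age_years = as.integer(x$age_years),
    sex = match_level(x$sex, SEX_LEVELS),
    bethesda = match_level(x$bethesda, BETHESDA_LEVELS),
    nodule_size_cm = as.numeric(x$nodule_size_cm),
    test_result = match_level(x$test_result, TEST_LEVELS),
    surgery = parse_flag(x$surgery),
    histology = match_level(x$histology, HISTOLOGY_LEVELS),
    histology_subtype = as.character(x$histology_subtype),
    followup_days = as.integer(x$followup_days),
    exclusion_flag = match_level(
      ifelse(is.na(x$exclusion_flag) | trimws(x$exclusion_flag) == "",
             "none", as.character(x$exclusion_flag)),
      EXCLUSION_LEVELS
    )
  )
  validate_nodule_cohort(out)
  structure(out, provenance = provenance,
            class = c("nodule_cohort", class(tibble::tibble())))
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "0")] <- FALSE
  out
}

validate_nodule_cohort <- function(x) {
  problems <- character(0)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      sprintf("row %d: %s", utils::head(rows, 5), msg)
    } else {
      character(0)
    }
  }
  problems <- c(
    problems,
    bad(is.na(x$nodule_id) | x$nodule_id == "", "missing nodule_id"),
    bad(is.na(x$sex), "invalid sex (expected female/male)"),
    bad(is.na(x$bethesda), "invalid bethesda class (expected III/IV)"),
    bad(is.na(x$test_result), "invalid test_result (expected negative/positive)"),
    bad(is.na(x$surgery), "invalid surgery flag (expected true/false)"),
    bad(is.na(x$histology),
        "invalid histology (expected benign/malignant/NIFTP/unavailable)"),
    bad(is.na(x$exclusion_flag), "invalid exclusion_flag"),
    bad(is.na(x$age_years) | x$age_years < 18, "age_years must be >= 18"),
    bad(!is.na(x$nodule_size_cm) & x$nodule_size_cm <= 0,
        "nodule_size_cm must be positive"),
    bad(!is.na(x$followup_days) & x$followup_days < 0,
        "followup_days must be non-negative"),
    bad(!is.na(x$surgery) & !x$surgery & !is.na(x$histology) &
          x$histology != "unavailable",
        "histology available without surgery"),
    bad(!is.na(x$histology) & x$histology == "NIFTP" &
          !is.na(x$surgery) & !x$surgery,
        "NIFTP requires surgery")
  )
  dup <- x$nodule_id[duplicated(x$nodule_id) & !is.na(x$nodule_id)]
  if (length(dup)) {
    problems <- c(problems, sprintf("duplicate nodule_id: %s",
                                    paste(unique(dup), collapse = ", ")))
  }
  if (length(problems)) {
    stop(paste0("invalid cohort:\n  ",
                paste(utils::head(problems, 10), collapse = "\n  ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a nodule cohort from CSV
#'
#' Reads a UTF-8 CSV with a header row into a validated [as_nodule_cohort()]
#' tibble. Enumerated values are matched case-insensitively; unknown columns
#' are dropped with a warning; a missing required column, an invalid value
#' (reported with its row number) or a duplicate `nodule_id` is an error.
#'
#' @param path Path to the cohort CSV.
#' @param provenance Source label; defaults to the file name.
#'
#' @return A `nodule_cohort` tibble.
#'
#' @examples
#' csv <- system.file("extdata", "study_cohort_synthetic.csv",
#'                    package = "thyverify")
#' cohort <- read_cohort(csv)
#' nrow(cohort) # 256
#' @export
read_cohort <- function(path, provenance = basename(path)) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  as_nodule_cohort(raw, provenance = provenance)
}

#' Write a nodule cohort to CSV
#'
#' Inverse of [read_cohort()]: writing then re-reading yields identical
#' records (missing optional values round-trip as empty fields).
#'
#' @param cohort A `nodule_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  readr::write_csv(tibble::as_tibble(cohort)[COHORT_COLUMNS], path, na = "")
  invisible(path)
}

#' Apply exclusion flags
#'
#' Removes records whose `exclusion_flag` is not `"none"` (collision tumors
#' with mixed benign/malignant components in one nodule; nodules whose
#' FNA-to-pathology correspondence could not be established). Flags are
#' supplied in the data -- the matching itself is a manual clinical step --
#' and an excluded record takes part in no analysis.
#'
#' @param cohort A `nodule_cohort`.
#'
#' @return A list with `cohort` (the analysis cohort, only unflagged records)
#'   and `log`, an `exclusion_log` with `n_input`, `n_excluded_by_reason`
#'   (named counts) and `n_analyzable`, which always reconcile:
#'   `n_input = n_analyzable + sum(n_excluded_by_reason)`.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  keep <- cohort$exclusion_flag == "none"
  reasons <- setdiff(EXCLUSION_LEVELS, "none")
  by_reason <- vapply(reasons,
                      function(r) sum(cohort$exclusion_flag == r), integer(1))
  log <- structure(
    list(n_input = nrow(cohort),
         n_excluded_by_reason = by_reason,
         n_analyzable = sum(keep)),
    class = "exclusion_log"
  )
  analysis <- cohort[keep, ]
  attr(analysis, "provenance") <- attr(cohort, "provenance")
  class(analysis) <- class(cohort)
  list(cohort = analysis, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("cohort exclusions: %d input -> %d analyzable\n",
              x$n_input, x$n_analyzable))
  for (r in names(x$n_excluded_by_reason)) {
    cat(sprintf("  %s: %d\n", r, x$n_excluded_by_reason[[r]]))
  }
  invisible(x)
}

#' Reference-standard truth label
#'
#' Maps histopathology outcomes to the truth classes used by every
#' performance computation. NIFTP -- an indolent encapsulated follicular
#' neoplasm whose diagnosis is only possible on the resected specimen -- is
#' counted as malignant, so a positive test on a NIFTP nodule is a true
#' positive. Unoperated nodules have no reference standard and are `unknown`.
#'
#' @param histology Character vector of histology values (`benign`,
#'   `malignant`, `NIFTP`, `unavailable`), or a `nodule_cohort` (its
#'   `histology` column is used).
#'
#' @return Character vector: `"malignant"`, `"benign"` or `"unknown"`.
#'
#' @examples
#' truth_label(c("NIFTP", "benign", "unavailable"))
#' @export
truth_label <- function(histology) {
  if (inherits(histology, "nodule_cohort")) histology <- histology$histology
  unname(c(benign = "benign", malignant = "malignant",
           NIFTP = "malignant", unavailable = "unknown")[histology])
}

#' Patient-level roll-up
#'
#' Descriptive convenience only: number of tested nodules per patient. All
#' performance and utility analyses are strictly nodule-level and never use
#' this summary.
#'
#' @param cohort A `nodule_cohort`.
#' @return A tibble with `patient_id` and `n_nodules`.
#' @export
patients_summary <- function(cohort) {
  stopifnot(inherits(cohort, "nodule_cohort"))
  dplyr::count(tibble::as_tibble(cohort), .data$patient_id,
               name = "n_nodules")
}
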