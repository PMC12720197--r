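# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: latent malignancy ~ Bernoulli(prevalence); an imperfect
# binary test; surgery selection depending only on the test result (the
# information structure the Bayes/Hall adjustment implicitly assumes);
# histology revealed only upon surgery. Covariates (age, sex, Bethesda class,
# nodule size) are drawn independently of truth -- they exercise the
# descriptive layer and encode no risk model.

#' Simulation parameters
#'
#' Defaults are the study-emulating stated world: 245 nodules, 25.1%
#' malignancy prevalence, test sensitivity/specificity 0.83/0.835 (the
#' adjusted-estimate scale), surgery probability 0.898 given a positive test
#' and 0.045 given a negative one, 78% Bethesda IV, 83.7% female, one
#' missing histopathology report per ~86 surgeries, ~4% NIFTP among operated
#' malignants, 11/256 collision-tumor rate, ages 20-90, log-normal nodule
#' sizes around 1.2 cm, follow-up 10-1451 days.
#'
#' @param n_nodules Number of records to generate (flagged collisions
#'   included).
#' @param prevalence Malignancy prevalence.
#' @param test_sensitivity,test_specificity Generative test operating
#'   characteristics.
#' @param p_surgery_given_positive,p_surgery_given_negative Surgery selection
#'   probabilities conditional on the test result.
#' @param p_histology_missing_given_surgery Probability an operated nodule
#'   has no accessible histopathology report.
#' @param niftp_fraction Fraction of operated malignant nodules recorded as
#'   NIFTP.
#' @param bethesda_iv_fraction,female_fraction Covariate marginals.
#' @param age_range Integer min/max age in years (min >= 18).
#' @param size_meanlog,size_sdlog Log-normal location/scale of nodule size
#'   (cm).
#' @param collision_fraction Fraction of records flagged `collision_tumor`.
#' @param followup_days_range Integer min/max follow-up for unoperated
#'   test-negative nodules.
#' @param truth_leakage Extra surgery probability for malignant test-negative
#'   nodules (default 0; the study's two false negatives were operated
#'   because of a co-existing test-positive nodule, so this knob exists for
#'   robustness experiments).
#' @param multi_nodule_fraction Fraction of patients carrying two nodules
#'   (default 0: one nodule per patient).
#' @param seed Integer RNG seed; identical parameters (seed included) yield
#'   byte-identical cohorts.
#'
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_nodules = 245,
                       prevalence = 0.251,
                       test_sensitivity = 0.83,
                       test_specificity = 0.835,
                       p_surgery_given_positive = 0.898,
                       p_surgery_given_negative = 0.045,
                       p_histology_missing_given_surgery = 1 / 86,
                       niftp_fraction = 2 / 49,
                       bethesda_iv_fraction = 0.78,
                       female_fraction = 0.837,
                       age_range = c(20L, 90L),
                       size_meanlog = log(1.1),
                       size_sdlog = 0.35,
                       collision_fraction = 11 / 256,
                       followup_days_range = c(10L, 1451L),
                       truth_leakage = 0,
                       multi_nodule_fraction = 0,
                       seed = 1L) {
  p <- list(n_nodules = as.integer(n_nodules), prevalence = prevalence,
            test_sensitivity = test_sensitivity,
            test_specificity = test_specificity,
            p_surgery_given_positive = p_surgery_given_positive,
            p_surgery_given_negative = p_surgery_given_negative,
            p_histology_missing_given_surgery = p_histology_missing_given_surgery,
            niftp_fraction = niftp_fraction,
            bethesda_iv_fraction = bethesda_iv_fraction,
            female_fraction = female_fraction,
            age_range = as.integer(age_range),
            size_meanlog = size_meanlog, size_sdlog = size_sdlog,
            collision_fraction = collision_fraction,
            followup_days_range = as.integer(followup_days_range),
            truth_leakage = truth_leakage,
            multi_nodule_fraction = multi_nodule_fraction,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fracs <- c("prevalence", "test_sensitivity", "test_specificity",
             "p_surgery_given_positive", "p_surgery_given_negative",
             "p_histology_missing_given_surgery", "niftp_fraction",
             "bethesda_iv_fraction", "female_fraction", "collision_fraction",
             "truth_leakage", "multi_nodule_fraction")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single fraction in [0, 1]", f),
           call. = FALSE)
    }
  }
  if (is.na(p$n_nodules) || p$n_nodules < 0) {
    stop("`n_nodules` must be a non-negative count", call. = FALSE)
  }
  if (length(p$age_range) != 2L || p$age_range[1] < 18L ||
      p$age_range[1] > p$age_range[2]) {
    stop("`age_range` must be an increasing pair with min >= 18", call. = FALSE)
  }
  if (length(p$followup_days_range) != 2L || p$followup_days_range[1] < 0L ||
      p$followup_days_range[1] > p$followup_days_range[2]) {
    stop("`followup_days_range` must be a non-negative increasing pair",
         call. = FALSE)
  }
  if (is.na(p$seed)) stop("`seed` must be an integer", call. = FALSE)
  invisible(p)
}

#' Read simulation parameters from a JSON config file
#'
#' The config is a flat JSON object whose keys are [sim_params()] argument
#' names; `seed` is mandatory for pipeline runs so outputs are reproducible.
#'
#' @param path Path to a JSON file.
#' @return A `sim_params` list.
#' @export
sim_params_from_file <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(formals(sim_params)))
  if (length(unknown)) {
    stop(sprintf("unknown simulation parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!"seed" %in% names(cfg)) {
    stop("simulation config must set `seed`", call. = FALSE)
  }
  do.call(sim_params, cfg)
}

#' Simulate a nodule cohort
#'
#' Generates a [as_nodule_cohort()] table under the generative model
#' described in [sim_params()]. Per nodule: truth ~ Bernoulli(prevalence);
#' test positive with probability `test_sensitivity` if malignant, else
#' `1 - test_specificity`; surgery ~ Bernoulli(p_surgery | test result, plus
#' `truth_leakage` for malignant test-negatives); histology equals the truth
#' label only if operated and the report is not missing; a `niftp_fraction`
#' of operated malignants is recorded as NIFTP (with subtype "NIFTP").
#' Subtype strings are drawn from [histology_vocabulary()] with study-like
#' weights. Follow-up days are drawn only for unoperated test-negatives.
#'
#' @param params A [sim_params()] object.
#' @return A `nodule_cohort` with `params$n_nodules` records (collision
#'   records carry `exclusion_flag = "collision_tumor"`).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  n <- p$n_nodules
  if (n == 0) {
    return(as_nodule_cohort(
      tibble::tibble(patient_id = character(), nodule_id = character(),
                     age_years = integer(), sex = character(),
                     bethesda = character(), nodule_size_cm = numeric(),
                     test_result = character(), surgery = logical(),
                     histology = character(),
                     histology_subtype = character(),
                     followup_days = integer(),
                     exclusion_flag = character()),
      provenance = sprintf("simulated (seed %d)", p$seed)))
  }

  malignant <- stats::rbinom(n, 1, p$prevalence) == 1
  p_pos <- ifelse(malignant, p$test_sensitivity, 1 - p$test_specificity)
  positive <- stats::rbinom(n, 1, p_pos) == 1
  p_surg <- ifelse(positive, p$p_surgery_given_positive,
                   pmin(1, p$p_surgery_given_negative +
                          ifelse(malignant, p$truth_leakage, 0)))
  surgery <- stats::rbinom(n, 1, p_surg) == 1
  missing_report <- surgery &
    stats::rbinom(n, 1, p$p_histology_missing_given_surgery) == 1
  verified <- surgery & !missing_report
  niftp <- verified & malignant &
    stats::rbinom(n, 1, p$niftp_fraction) == 1

  histology <- rep("unavailable", n)
  histology[verified & malignant] <- "malignant"
  histology[verified & !malignant] <- "benign"
  histology[niftp] <- "NIFTP"

  vocab <- histology_vocabulary()
  benign_types <- vocab$subtype[vocab$class == "benign"]
  malignant_types <- setdiff(vocab$subtype[vocab$class == "malignant"],
                             "NIFTP")
  # study-like subtype mix: follicular adenoma dominates benign resections,
  # follicular-variant papillary carcinoma the malignant ones
  benign_w <- c(25, 2, 5, 2) / 34
  malignant_w <- c(39, 2, 1, 1, 1, 5) / 49
  subtype <- rep(NA_character_, n)
  nb <- sum(histology == "benign")
  if (nb) subtype[histology == "benign"] <-
      sample(benign_types, nb, replace = TRUE, prob = benign_w)
  nm <- sum(histology == "malignant")
  if (nm) subtype[histology == "malignant"] <-
      sample(malignant_types, nm, replace = TRUE, prob = malignant_w)
  subtype[histology == "NIFTP"] <- "NIFTP"

  followup <- rep(NA_integer_, n)
  fu_idx <- !positive & !surgery
  if (any(fu_idx)) {
    followup[fu_idx] <- sample(seq(p$followup_days_range[1],
                                   p$followup_days_range[2]),
                               sum(fu_idx), replace = TRUE)
  }

  patient_id <- sprintf("SIM-P%05d", seq_len(n))
  if (p$multi_nodule_fraction > 0 && n >= 2) {
    # pair up a fraction of consecutive records under one patient id
    n_pairs <- floor(p$multi_nodule_fraction * n / 2)
    if (n_pairs > 0) {
      for (k in seq_len(n_pairs)) {
        patient_id[2 * k] <- patient_id[2 * k - 1]
      }
    }
  }

  as_nodule_cohort(tibble::tibble(
    patient_id = patient_id,
    nodule_id = sprintf("SIM-N%05d", seq_len(n)),
    age_years = sample(seq(p$age_range[1], p$age_range[2]), n, replace = TRUE),
    sex = ifelse(stats::rbinom(n, 1, p$female_fraction) == 1,
                 "female", "male"),
    bethesda = ifelse(stats::rbinom(n, 1, p$bethesda_iv_fraction) == 1,
                      "IV", "III"),
    nodule_size_cm = round(stats::rlnorm(n, p$size_meanlog, p$size_sdlog), 2),
    test_result = ifelse(positive, "positive", "negative"),
    surgery = surgery,
    histology = histology,
    histology_subtype = subtype,
    followup_days = followup,
    exclusion_flag = ifelse(stats::rbinom(n, 1, p$collision_fraction) == 1,
                            "collision_tumor", "none")
  ), provenance = sprintf("simulated (seed %d)", p$seed))
}

#' Closed-form Bayes negative predictive value
#'
#' The population NPV implied by prevalence and the test's operating
#' characteristics: `Sp (1 - p) / (Sp (1 - p) + (1 - Se) p)`. Used as the
#' generative truth in bias experiments.
#'
#' @param prevalence,sensitivity,specificity Generative parameters.
#' @return The true NPV.
#' @export
bayes_npv <- function(prevalence, sensitivity, specificity) {
  specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
}

#' Monte-Carlo bias experiment: naive vs adjusted estimators
#'
#' For each replicate: simulate a cohort, apply exclusions, tally the
#' verified 2x2, and compute both the naive (operated-only) and the
#' verification-adjusted performance reports. Summaries compare each
#' estimator of sensitivity, specificity and NPV against the generative
#' truth (`test_sensitivity`, `test_specificity`, and [bayes_npv()]).
#'
#' Replicates where an estimator's denominator is empty are recorded as
#' `NA` and excluded from that estimator's summaries, with a count.
#'
#' @param params Generative [sim_params()]; per-replicate seeds are derived
#'   from `params$seed`.
#' @param n_replicates Number of replicates (>= 1).
#' @param external_sensitivity Sensitivity fed to the imputation; defaults to
#'   the generative `params$test_sensitivity`.
#' @param conf_level Confidence level used for the per-replicate intervals
#'   (for empirical coverage).
#'
#' @return A `bias_study` list: `replicates` (tibble of per-replicate
#'   estimates), `summary` (tibble: estimator x metric with `mean`, `bias`,
#'   `rmse`, `coverage`, `n_used`), `truth`, `params`, `n_replicates`.
#' @export
bias_experiment <- function(params = sim_params(), n_replicates = 100,
                            external_sensitivity = params$test_sensitivity,
                            conf_level = 0.95) {
  stopifnot(inherits(params, "sim_params"), n_replicates >= 1)
  cfg <- adjustment_config(external_sensitivity)
  rep_seeds <- withr::with_seed(
    params$seed, sample.int(.Machine$integer.max - 1L, n_replicates))

  one <- function(i) {
    pi <- params
    pi$seed <- rep_seeds[i]
    cohort <- apply_exclusions(simulate_cohort(pi))$cohort
    v <- tally_verified(cohort)
    row <- list(replicate = i)
    for (mode in c("naive", "adjusted")) {
      rep_obj <- tryCatch({
        x <- if (mode == "naive") v else adjust_counts(v, cfg)
        compute_performance(x, conf_level)
      }, error = function(e) NULL)
      for (m in c("sensitivity", "specificity", "npv")) {
        pr <- if (is.null(rep_obj)) NULL else rep_obj$metrics[[m]]
        ok <- !is.null(pr) && pr$defined
        row[[paste0(mode, "_", m)]] <- if (ok) pr$estimate else NA_real_
        row[[paste0(mode, "_", m, "_low")]] <- if (ok) pr$conf_low else NA_real_
        row[[paste0(mode, "_", m, "_high")]] <- if (ok) pr$conf_high else NA_real_
      }
    }
    tibble::as_tibble(row)
  }
  reps <- dplyr::bind_rows(lapply(seq_len(n_replicates), one))

  truth <- c(
    sensitivity = params$test_sensitivity,
    specificity = params$test_specificity,
    npv = bayes_npv(params$prevalence, params$test_sensitivity,
                    params$test_specificity)
  )
  summ <- list()
  for (mode in c("naive", "adjusted")) {
    for (m in names(truth)) {
      est <- reps[[paste0(mode, "_", m)]]
      lo <- reps[[paste0(mode, "_", m, "_low")]]
      hi <- reps[[paste0(mode, "_", m, "_high")]]
      use <- !is.na(est)
      tru <- truth[[m]]
      est_mean <- mean(est[use])
      summ[[paste(mode, m)]] <- tibble::tibble(
        estimator = mode, metric = m, truth = tru,
        mean = est_mean,
        bias = est_mean - tru,
        rmse = sqrt(mean((est[use] - tru)^2)),
        coverage = mean(lo[use] <= tru & tru <= hi[use]),
        mc_se = stats::sd(est[use]) / sqrt(sum(use)),
        n_used = sum(use),
        n_undefined = sum(!use)
      )
    }
  }
  structure(list(replicates = reps, summary = dplyr::bind_rows(summ),
                 truth = truth, params = params,
                 external_sensitivity = external_sensitivity,
                 n_replicates = n_replicates),
            class = "bias_study")
}

#' @export
print.bias_study <- function(x, ...) {
  cat(sprintf("verification-bias experiment: %d replicates, n = %d per cohort\n",
              x$n_replicates, x$params$n_nodules))
  cat(sprintf("  generative Se %.3f, Sp %.3f, prevalence %.3f; external Se %.3f\n",
              x$params$test_sensitivity, x$params$test_specificity,
              x$params$prevalence, x$external_sensitivity))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %-11s truth %.3f  mean %.3f  bias %+.3f  rmse %.3f  coverage %.2f (n=%d)\n",
                s$estimator[i], s$metric[i], s$truth[i], s$mean[i],
                s$bias[i], s$rmse[i], s$coverage[i], s$n_used[i]))
  }
  invisible(x)
}
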