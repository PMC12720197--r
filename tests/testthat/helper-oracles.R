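# Independent oracles used across the suite.

# Clopper-Pearson by bisection over exact binomial tail probabilities:
# the lower bound solves P(X >= x | p) = alpha/2, the upper bound
# P(X <= x | p) = alpha/2. Independent of the Beta-quantile route.
cp_bisection_oracle <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (x == n) 1 else {
    stats::uniroot(function(p) pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Two-sided Fisher p by full enumeration of margin-preserving tables
# (probability-mass criterion with 1e-7 relative tie tolerance).
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(k, r1, n - r1, c1)
  sum(pr[pr <= dhyper(a, r1, n - r1, c1) * (1 + 1e-7)])
}

# Minimal valid cohort rows for construction tests.
cohort_row <- function(nodule_id = "N1", patient_id = "P1", age_years = 40,
                       sex = "female", bethesda = "III",
                       test_result = "negative", surgery = FALSE,
                       histology = "unavailable",
                       histology_subtype = NA_character_,
                       nodule_size_cm = 1.0, followup_days = NA_integer_,
                       exclusion_flag = "none") {
  tibble::tibble(patient_id = patient_id, nodule_id = nodule_id,
                 age_years = age_years, sex = sex, bethesda = bethesda,
                 nodule_size_cm = nodule_size_cm, test_result = test_result,
                 surgery = surgery, histology = histology,
                 histology_subtype = histology_subtype,
                 followup_days = followup_days,
                 exclusion_flag = exclusion_flag)
}

make_cohort <- function(...) {
  as_nodule_cohort(dplyr::bind_rows(...), provenance = "test")
}

# The analysis cohort of the bundled study replica.
replica_analysis <- function() {
  apply_exclusions(study_replica_cohort())$cohort
}
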