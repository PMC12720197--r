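# Exact small-sample statistics: Clopper-Pearson intervals, Fisher's exact
# test, Pearson chi-square. These back every confidence interval and
# association p-value the package reports.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Computes the exact (Clopper-Pearson) confidence interval for a binomial
#' proportion from the Beta-quantile closed form: the lower bound is the
#' `alpha/2` quantile of `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper
#' bound the `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`),
#' with `alpha = 1 - conf_level`. The interval inverts the binomial tail
#' probabilities exactly, so its coverage is never below the nominal level.
#'
#' @param x Number of successes (vectorised; `0 <= x <= n`).
#' @param n Number of trials (`n >= 1`, recycled against `x`).
#' @param conf_level Confidence level, a single number in (0, 1).
#'
#' @return A tibble with one row per element of `x` and columns `lower`,
#'   `upper`, `conf_level`.
#'
#' @examples
#' clopper_pearson(49, 59) # 0.710 - 0.916
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (!is.numeric(x) || !is.numeric(n)) {
    stop("`x` and `n` must be numeric", call. = FALSE)
  }
  if (length(conf_level) != 1L || !is.finite(conf_level) ||
      conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  k <- max(length(x), length(n))
  x <- rep_len(x, k)
  n <- rep_len(n, k)
  if (any(n < 1) || any(x < 0) || any(x > n)) {
    stop("require 0 <= x <= n and n >= 1", call. = FALSE)
  }
  alpha <- 1 - conf_level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(lower = lower, upper = upper, conf_level = conf_level)
}

#' Proportion with exact confidence interval
#'
#' Bundles a numerator/denominator pair with its point estimate and
#' Clopper-Pearson interval. This is the universal result carrier for every
#' rate the package reports (call rates, performance metrics, concordance and
#' surgery-avoidance rates).
#'
#' A zero denominator is permitted and yields an undefined proportion
#' (`defined = FALSE`, `NA` estimate and bounds), printed as "not applicable";
#' downstream reporting never coerces an undefined rate to 0.
#'
#' @param x Non-negative integer numerator.
#' @param n Non-negative integer denominator (`n >= x`).
#' @param conf_level Confidence level for the interval.
#'
#' @return An object of class `proportion`: a list with `numerator`,
#'   `denominator`, `estimate`, `conf_low`, `conf_high`, `conf_level`,
#'   `defined`.
#'
#' @examples
#' proportion_ci(88, 245) # malignant call rate 35.9%
#' @export
proportion_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, is.numeric(x), is.numeric(n))
  if (n < 0 || x < 0 || x > n) {
    stop("require 0 <= x <= n", call. = FALSE)
  }
  if (n == 0) {
    out <- list(numerator = 0L, denominator = 0L, estimate = NA_real_,
                conf_low = NA_real_, conf_high = NA_real_,
                conf_level = conf_level, defined = FALSE)
  } else {
    ci <- clopper_pearson(x, n, conf_level)
    out <- list(numerator = as.integer(x), denominator = as.integer(n),
                estimate = x / n, conf_low = ci$lower, conf_high = ci$upper,
                conf_level = conf_level, defined = TRUE)
  }
  structure(out, class = "proportion")
}

#' @export
print.proportion <- function(x, ...) {
  if (!x$defined) {
    cat("proportion: not applicable (zero denominator)\n")
    return(invisible(x))
  }
  cat(sprintf("%d/%d = %s%% (%g%% CI: %s-%s)\n",
              x$numerator, x$denominator, fmt_pct(x$estimate),
              100 * x$conf_level, fmt_pct(x$conf_low), fmt_pct(x$conf_high)))
  invisible(x)
}

#' @export
format.proportion <- function(x, ...) {
  if (!x$defined) return("NA")
  sprintf("%s (%s-%s)", fmt_pct(x$estimate),
          fmt_pct(x$conf_low), fmt_pct(x$conf_high))
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) {
    stop("table has zero grand total", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of independence: the p-value is the sum of
#' hypergeometric probabilities, over all tables with the observed margins, of
#' tables whose probability does not exceed that of the observed table
#' (probability-mass criterion, with a 1e-7 relative tolerance for ties --
#' the common two-sided convention).
#'
#' @param tab A 2x2 matrix (or coercible) of non-negative integer counts with
#'   a positive grand total.
#'
#' @return The two-sided p-value, a single number in (0, 1].
#'
#' @examples
#' fisher_exact_2x2(matrix(c(150, 9, 7, 79), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-square test of independence
#'
#' For an r x c contingency table, computes
#' `sum((|O - E| - adj)^2 / E)` with `adj = 0.5` for the Yates-corrected 2x2
#' case and 0 otherwise, and refers it to the chi-square distribution with
#' `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param tab Contingency table of non-negative integer counts, at least 2x2.
#' @param correct Apply the continuity correction (2x2 tables only)?
#'
#' @return A list with `statistic`, `df`, `p_value`.
#'
#' @examples
#' pearson_chi2(matrix(c(81, 58, 76, 30), nrow = 2, byrow = TRUE),
#'              correct = TRUE) # Table-1 style age association, p ~ 0.04
#' @export
pearson_chi2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("expected at least a 2x2 table", call. = FALSE)
  }
  if (any(!is.finite(tab)) || any(tab < 0)) {
    stop("table cells must be non-negative", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: expected counts undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Default association test for a 2x2 table
#'
#' Reporting-layer rule for descriptive tables: continuity-corrected
#' chi-square by default, Fisher's exact test when any expected cell count is
#' below 5.
#'
#' @param tab A 2x2 table of counts.
#' @return A list with `method` ("chi-square (corrected)" or "Fisher exact")
#'   and `p_value`.
#' @export
assoc_test_2x2 <- function(tab) {
  tab <- check_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(method = "Fisher exact", p_value = fisher_exact_2x2(tab))
  } else {
    ch <- pearson_chi2(tab, correct = TRUE)
    list(method = "chi-square (corrected)", p_value = ch$p_value)
  }
}

# Half-up rounding (the convention used by the tables this package renders;
# base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a fraction as a percentage at 1 decimal, half-up.
fmt_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(100 * x, digits))
}

# Paper-style p-value display: two significant figures, floored at <0.001,
# ceiling at >0.9. Full precision is retained everywhere else.
fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) return("<0.001")
  if (p > 0.9) return(">0.9")
  format(signif(p, 2), scientific = FALSE)
}
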