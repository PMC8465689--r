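# Statistical layer: 2x2 odds ratios with Woolf (log-scale) confidence
# intervals, Pearson chi-square homogeneity tests, the Cochran-Armitage
# trend test for ordered proportions, one-way ANOVA with Bonferroni
# pairwise comparisons, retention rates by engagement group, and logistic
# cessation models under missing-outcome-as-smoking coding.

#' Odds ratio for a 2x2 table with Woolf confidence interval
#'
#' The cross-product odds ratio `(a*d)/(b*c)` with the log-scale (Woolf)
#' confidence interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`
#' and a two-sided Wald P value. Cells are exposed/unexposed successes and
#' failures: `a` successes and `b` failures in the exposed group, `c`
#' successes and `d` failures in the reference group. Zero cells are an
#' error; no continuity correction is applied silently.
#'
#' @param a,b,c,d Strictly positive integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `method`.
#' @export
#' @examples
#' odds_ratio_2x2(30, 123, 35, 244)
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers",
          class = "engagerx_validation_error")
  }
  if (any(counts == 0)) {
    abort(
      "zero cell in 2x2 table; the Woolf interval is undefined (an exact method would be needed)",
      class = "engagerx_zero_cell_error"
    )
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    estimate = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se),
    p_value = 2 * pnorm(-abs(log(est) / se)),
    method = "odds_ratio_woolf"
  )
}

#' Pearson chi-square test of homogeneity
#'
#' Tests whether the distribution over row categories is the same across
#' (ordered or unordered) column groups, via the Pearson statistic
#' `sum((O - E)^2 / E)` with `(r-1)(c-1)` degrees of freedom and no
#' continuity correction. Rows for missing categories should be dropped by
#' the caller before testing.
#'
#' @param tab A numeric matrix of non-negative counts, at least 2x2, with
#'   strictly positive row and column margins.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("contingency table must be at least 2x2",
          class = "engagerx_validation_error")
  }
  if (any(is.na(tab)) || any(tab < 0)) {
    abort("counts must be non-negative and non-missing",
          class = "engagerx_validation_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row or column margin in contingency table",
          class = "engagerx_zero_margin_error")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    method = "pearson_chi_square"
  )
}

#' Cochran-Armitage test for trend in proportions
#'
#' Tests for a linear trend in success proportions across ordered groups.
#' With scores `s_i`, the statistic is
#' `Z = sum(s_i (x_i - n_i p)) / sqrt(p (1-p) (sum(n_i s_i^2) - (sum(n_i s_i))^2 / N))`
#' where `p` is the pooled proportion; the P value is two-sided normal.
#' With two groups, `Z^2` equals the uncorrected Pearson chi-square of the
#' 2x2 table.
#'
#' @param successes,totals Integer vectors (same length >= 2) of successes
#'   and group sizes, in group order.
#' @param scores Numeric scores for the ordered groups; default equally
#'   spaced `0, 1, ..., k-1`.
#' @return A one-row tibble: `statistic` (Z, positive when proportions
#'   increase with score), `p_value`, `method`.
#' @export
cochran_armitage_trend <- function(successes, totals,
                                   scores = seq_along(successes) - 1) {
  k <- length(successes)
  if (k < 2 || length(totals) != k || length(scores) != k) {
    abort("need >= 2 groups with matching successes, totals and scores",
          class = "engagerx_validation_error")
  }
  if (any(totals <= 0) || any(successes < 0) || any(successes > totals)) {
    abort("require 0 <= successes <= totals with positive totals",
          class = "engagerx_validation_error")
  }
  n <- sum(totals)
  p <- sum(successes) / n
  if (p == 0 || p == 1) {
    abort("pooled proportion is degenerate (all successes or all failures)",
          class = "engagerx_validation_error")
  }
  num <- sum(scores * (successes - totals * p))
  den <- p * (1 - p) * (sum(totals * scores^2) - sum(totals * scores)^2 / n)
  if (den <= 0) {
    abort("trend test undefined: zero score variance across groups",
          class = "engagerx_validation_error")
  }
  z <- num / sqrt(den)
  tibble(
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    method = "cochran_armitage"
  )
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Tests the overall effect of a categorical factor on a numeric metric
#' (one-way ANOVA F test), and compares every pair of categories with
#' pooled-variance t tests whose P values are Bonferroni-adjusted
#' (multiplied by the number of pairs, capped at 1).
#'
#' @param data A data frame.
#' @param value Column (unquoted) holding the numeric metric; missing
#'   values are dropped.
#' @param group Column (unquoted) holding the grouping factor.
#' @return An object of class `anova_bonferroni`: a list with `overall`
#'   (tibble: `statistic`, `df1`, `df2`, `p_value`) and `pairwise` (tibble:
#'   `group1`, `group2`, `mean_diff`, `p_value`, `p_adjusted`).
#' @export
anova_bonferroni <- function(data, value, group) {
  value <- enquo(value)
  group <- enquo(group)
  d <- data |>
    transmute(value = as.numeric(!!value),
              group = factor(!!group)) |>
    filter(!is.na(.data$value), !is.na(.data$group)) |>
    mutate(group = droplevels(.data$group))
  counts <- table(d$group)
  if (length(counts) < 2 || any(counts < 1)) {
    abort("need at least 2 non-empty groups", class = "engagerx_validation_error")
  }
  fit <- aov(value ~ group, data = d)
  a <- anova(fit)
  overall <- tibble(
    statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
    p_value = a$`Pr(>F)`[1]
  )
  # Pooled-variance pairwise t tests sharing the ANOVA residual variance.
  lev <- levels(d$group)
  mse <- a$`Mean Sq`[2]
  dfr <- a$Df[2]
  means <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- unname(means[g1] - means[g2])
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tval <- diff / se
    p <- 2 * pt(-abs(tval), dfr)
    tibble(group1 = g1, group2 = g2, mean_diff = diff,
           p_value = p, p_adjusted = min(p * n_pairs, 1))
  })
  structure(list(overall = overall, pairwise = pairwise),
            class = "anova_bonferroni")
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, P = %.4g\n",
              x$overall$df1, x$overall$df2, x$overall$statistic,
              x$overall$p_value))
  cat(sprintf("Bonferroni pairwise comparisons (%d pairs):\n",
              nrow(x$pairwise)))
  print(as.data.frame(x$pairwise), ...)
  invisible(x)
}

#' Retention rate by engagement group, with trend test
#'
#' Retention is the fraction of users completing the follow-up outcome
#' survey (1 - dropout rate). Rates are computed per group of an ordered
#' engagement factor, and a Cochran-Armitage trend test with equally
#' spaced scores is run across the ordered groups, excluding the sentinel
#' categories `no_rating` and `ineligible` (which carry no ordering
#' information).
#'
#' @param cohort A per-user tibble with a logical `survey_completed`
#'   column and the grouping column.
#' @param group Column (unquoted) holding the ordered engagement factor.
#' @return An object of class `retention_result`: list with `rates`
#'   (tibble: group, `n`, `n_completed`, `retention`) and `trend` (tibble
#'   from [cochran_armitage_trend()], or `NULL` if fewer than 2 ordered
#'   groups).
#' @export
retention_by_level <- function(cohort, group) {
  group <- rlang::ensym(group)
  gname <- as_name(group)
  d <- cohort |>
    transmute(group = factor(!!group),
              survey_completed = .data$survey_completed) |>
    filter(!is.na(.data$group))
  rates <- d |>
    summarise(
      n = dplyr::n(),
      n_completed = sum(.data$survey_completed),
      retention = mean(.data$survey_completed),
      .by = "group"
    ) |>
    arrange(.data$group) |>
    rename(!!gname := "group")
  if (any(rates$n == 0)) {
    abort("empty group in retention computation",
          class = "engagerx_validation_error")
  }
  ordered <- rates |>
    filter(!.data[[gname]] %in% c("no_rating", "ineligible"))
  trend <- if (nrow(ordered) >= 2) {
    # degenerate pooled proportions (all retained / none retained) carry no
    # trend information
    tryCatch(cochran_armitage_trend(ordered$n_completed, ordered$n),
             error = function(e) NULL)
  } else {
    NULL
  }
  structure(list(rates = rates, trend = trend, group = gname),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat("Retention by", x$group, "\n")
  print(as.data.frame(x$rates), ...)
  if (!is.null(x$trend)) {
    cat(sprintf("Cochran-Armitage trend: Z = %.3f, P = %.4g\n",
                x$trend$statistic, x$trend$p_value))
  }
  invisible(x)
}

# Outcome coding: dropouts and participants missing the cessation outcome
# count as smoking.
code_cessation <- function(cohort) {
  as.integer(cohort$survey_completed &
               !is.na(cohort$abstinent_7day) & cohort$abstinent_7day)
}

default_adjustment <- function(exposure) {
  switch(exposure,
    level = c("age_group", "african_american", "cigs_per_day",
              "unsubscribed", "n_received"),
    rating_bin = c("african_american", "unsubscribed", "n_received")
  )
}

#' Logistic cessation model with missing-outcome-as-smoking coding
#'
#' Fits a maximum-likelihood logistic regression of 7-day point prevalence
#' abstinence on an engagement exposure. Participants who did not complete
#' the outcome survey are coded as smoking. The exposure is either the
#' engagement `level` (reference `none`) or the mean-rating `rating_bin`
#' (reference `low`, with unrated users carried as the `no_rating`
#' category). The adjusted model adds baseline confounders plus the
#' unsubscribe flag and the number of messages received; the default
#' adjustment set depends on the exposure (age group, race and cigarettes
#' per day are included for the response-rate exposure; race only for the
#' rating exposure).
#'
#' @param cohort Per-user tibble containing `survey_completed`,
#'   `abstinent_7day`, the exposure column, and any adjustment columns
#'   (see [build_cohort()]).
#' @param exposure `"level"` or `"rating_bin"`.
#' @param adjusted Fit the covariate-adjusted model?
#' @param covariates Character vector of adjustment columns; `NULL` uses
#'   the exposure-specific default.
#' @return An object of class `cessation_fit` wrapping the `glm` fit; use
#'   [exposure_effects()] or `tidy()` to extract odds ratios.
#' @export
fit_cessation_model <- function(cohort, exposure = c("level", "rating_bin"),
                                adjusted = FALSE, covariates = NULL) {
  exposure <- match.arg(exposure)
  if (!exposure %in% names(cohort)) {
    abort(paste0("cohort lacks exposure column '", exposure, "'"),
          class = "engagerx_validation_error")
  }
  covariates <- if (adjusted) covariates %||% default_adjustment(exposure) else character()
  ref <- if (exposure == "level") "none" else "low"
  d <- cohort |>
    mutate(
      .quit = code_cessation(cohort),
      .exposure = relevel(factor(.data[[exposure]]), ref = ref)
    )
  empty <- setdiff(levels(d$.exposure), as.character(d$.exposure))
  if (length(empty) > 0) {
    d$.exposure <- droplevels(d$.exposure)
    if (nlevels(d$.exposure) < 2) {
      abort("exposure has fewer than 2 populated categories",
            class = "engagerx_validation_error")
    }
  }
  for (cv in covariates) {
    if (!cv %in% names(d)) {
      abort(paste0("adjustment covariate '", cv, "' missing from cohort"),
            class = "engagerx_validation_error")
    }
  }
  rhs <- paste(c(".exposure", covariates), collapse = " + ")
  fit <- glm(
    stats::as.formula(paste(".quit ~", rhs)),
    family = binomial(),
    data = d,
    control = glm.control(epsilon = 1e-8, maxit = 100)
  )
  if (!fit$converged) {
    abort("logistic model did not converge within 100 iterations",
          class = "engagerx_convergence_error")
  }
  if (any(abs(coef(fit)) > 15, na.rm = TRUE) || anyNA(coef(fit))) {
    abort(
      "apparent separation in logistic model (unbounded or aliased coefficient); check exposure/covariate cell counts",
      class = "engagerx_separation_error"
    )
  }
  structure(
    list(fit = fit, exposure = exposure, adjusted = adjusted,
         covariates = covariates, reference = ref,
         n = nrow(d), n_events = sum(d$.quit)),
    class = "cessation_fit"
  )
}

#' Exposure odds ratios from a fitted cessation model
#'
#' Extracts per-category odds ratios (exponentiated coefficients) with Wald
#' 95% confidence intervals and P values for the exposure, including the
#' reference row.
#'
#' @param object A [fit_cessation_model()] fit.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `category`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `reference`.
#' @export
exposure_effects <- function(object, conf_level = 0.95) {
  stopifnot(inherits(object, "cessation_fit"))
  fit <- object$fit
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  idx <- grep("^\\.exposure", names(cf))
  categories <- sub("^\\.exposure", "", names(cf)[idx])
  b <- unname(cf[idx])
  s <- unname(se[idx])
  tibble(
    category = c(object$reference, categories),
    estimate = c(NA_real_, exp(b)),
    ci_low = c(NA_real_, exp(b - z * s)),
    ci_high = c(NA_real_, exp(b + z * s)),
    p_value = c(NA_real_, 2 * pnorm(-abs(b / s))),
    reference = c(TRUE, rep(FALSE, length(idx)))
  )
}

#' @export
print.cessation_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic cessation model (missing outcome = smoking)\n  exposure: %s (reference %s)%s\n  n = %d, events = %d\n",
    x$exposure, x$reference,
    if (x$adjusted) paste0("; adjusted for ", paste(x$covariates, collapse = ", ")) else " (unadjusted)",
    x$n, x$n_events
  ))
  print(as.data.frame(exposure_effects(x)), digits = 3)
  invisible(x)
}
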