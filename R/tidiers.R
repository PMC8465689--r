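# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cessation model fit
#'
#' @param x A [fit_cessation_model()] object.
#' @param exponentiate Return odds ratios (default) rather than log-odds
#'   coefficients.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per model coefficient: `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`, `ci_low`, `ci_high`.
#' @method tidy cessation_fit
#' @export
tidy.cessation_fit <- function(x, exponentiate = TRUE, conf_level = 0.95,
                               ...) {
  cf <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  stat <- cf / se
  out <- tibble(
    term = sub("^\\.exposure", paste0(x$exposure, ":"), names(cf)),
    estimate = unname(cf),
    std_error = unname(se),
    statistic = unname(stat),
    p_value = unname(2 * pnorm(-abs(stat))),
    ci_low = unname(cf - z * se),
    ci_high = unname(cf + z * se)
  )
  if (exponentiate) {
    out <- mutate(out, dplyr::across(c("estimate", "ci_low", "ci_high"), exp))
  }
  out
}

#' Glance at a cessation model fit
#'
#' @param x A [fit_cessation_model()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `exposure`, `adjusted`,
#'   `null_deviance`, `deviance`, `aic`, `df_residual`, `converged`.
#' @method glance cessation_fit
#' @export
glance.cessation_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_events = x$n_events,
    exposure = x$exposure,
    adjusted = x$adjusted,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    df_residual = x$fit$df.residual,
    converged = x$fit$converged
  )
}

#' Tidy an ANOVA-with-Bonferroni result
#'
#' @param x An [anova_bonferroni()] object.
#' @param ... Unused.
#' @return The pairwise comparison tibble: `group1`, `group2`,
#'   `mean_diff`, `p_value`, `p_adjusted`.
#' @method tidy anova_bonferroni
#' @export
tidy.anova_bonferroni <- function(x, ...) {
  x$pairwise
}

#' Glance at an ANOVA-with-Bonferroni result
#'
#' @param x An [anova_bonferroni()] object.
#' @param ... Unused.
#' @return The one-row overall tibble: `statistic`, `df1`, `df2`,
#'   `p_value`.
#' @method glance anova_bonferroni
#' @export
glance.anova_bonferroni <- function(x, ...) {
  x$overall
}

#' Tidy a retention-by-group result
#'
#' @param x A [retention_by_level()] object.
#' @param ... Unused.
#' @return The per-group rates tibble.
#' @method tidy retention_result
#' @export
tidy.retention_result <- function(x, ...) {
  x$rates
}
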