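# Behavioral engagement metrics: per-user response rates, the four-level
# response-rate binning (none / low / medium / high), first/last-message
# response flags, and monthly trend summaries over the 6-month follow-up.

#' Per-user response rates
#'
#' The response rate is the number of messages a user rated divided by the
#' number of messages the user received (every send counts, including
#' re-sends of previously unrated messages). It is undefined (`NA`) for a
#' user with no events, which is distinct from a rate of zero.
#'
#' @param events Validated event log.
#' @return A tibble with one row per user appearing in `events`:
#'   `user_id`, `n_received`, `n_rated`, `response_rate`.
#' @export
response_rates <- function(events) {
  validate_events(events) |>
    summarise(
      n_received = dplyr::n(),
      n_rated = sum(!is.na(.data$rating)),
      .by = "user_id"
    ) |>
    mutate(response_rate = ifelse(.data$n_received > 0,
                                  .data$n_rated / .data$n_received, NA_real_))
}

#' Response-rate level binning
#'
#' Four ordered engagement levels partition the response-rate scale:
#' `none` (exactly 0), `low` (> 0 and <= `cut_low`), `medium`
#' (> `cut_low` and <= `cut_mid`), `high` (> `cut_mid` and <= 1). The
#' default cutoffs 0.1 and 0.6 are the one-decimal values closest to the
#' non-zero response-rate tertiles in the cohort this scheme was developed
#' on; [derive_cutoffs()] recomputes them for a new cohort.
#'
#' @param cut_low,cut_mid Upper bounds of the low and medium bins; must
#'   satisfy `0 < cut_low < cut_mid <= 1`.
#' @param derivation `"fixed"` or `"data_driven"`.
#' @return A `level_binning` object.
#' @export
level_binning <- function(cut_low = 0.1, cut_mid = 0.6, derivation = "fixed") {
  if (!(is.numeric(cut_low) && is.numeric(cut_mid) &&
        cut_low > 0 && cut_low < cut_mid && cut_mid <= 1)) {
    abort("level binning requires 0 < cut_low < cut_mid <= 1",
          class = "engagerx_degenerate_binning")
  }
  structure(
    list(cut_low = cut_low, cut_mid = cut_mid,
         derivation = match.arg(derivation, c("fixed", "data_driven"))),
    class = "level_binning"
  )
}

#' @export
print.level_binning <- function(x, ...) {
  cat(sprintf(
    "<level_binning> none: 0 | low: (0, %.1f] | medium: (%.1f, %.1f] | high: (%.1f, 1] (%s)\n",
    x$cut_low, x$cut_low, x$cut_mid, x$cut_mid, x$derivation
  ))
  invisible(x)
}

# Snap a value to the closest point of the one-decimal grid 0.1, ..., 1.0,
# breaking ties toward the lower grid value.
snap_to_grid <- function(q) {
  grid <- seq(0.1, 1, by = 0.1)
  d <- abs(grid - q)
  grid[which(d <= min(d) + 1e-12)[1]]
}

#' Derive level cutoffs from non-zero response rates
#'
#' Data-driven binning: computes the tertiles (1/3 and 2/3 quantiles, linear
#' interpolation on the sorted sample, the conventional "type 7" rule) of
#' the non-zero response rates, then snaps each tertile to the closest value
#' on the one-decimal grid 0.1, ..., 1.0 (ties toward the lower value).
#'
#' @param nonzero_rates Numeric vector of response rates in (0, 1].
#' @return A `level_binning` with `derivation = "data_driven"`.
#' @export
#' @examples
#' derive_cutoffs(c(0.05, 0.1, 0.2, 0.4, 0.5, 0.7, 0.8, 0.9, 1.0))
derive_cutoffs <- function(nonzero_rates) {
  if (length(nonzero_rates) == 0) {
    abort("cannot derive cutoffs from an empty rate vector",
          class = "engagerx_degenerate_binning")
  }
  if (any(is.na(nonzero_rates)) || any(nonzero_rates <= 0 | nonzero_rates > 1)) {
    abort("nonzero_rates must all lie in (0, 1]",
          class = "engagerx_validation_error")
  }
  q <- quantile(nonzero_rates, probs = c(1 / 3, 2 / 3), type = 7, names = FALSE)
  cl <- snap_to_grid(q[1])
  cm <- snap_to_grid(q[2])
  if (cl >= cm) {
    abort(sprintf(
      "degenerate binning: snapped tertiles coincide (%.1f, %.1f); the rate distribution is too concentrated for 3 non-zero levels",
      cl, cm
    ), class = "engagerx_degenerate_binning")
  }
  level_binning(cl, cm, derivation = "data_driven")
}

#' Assign response rates to engagement levels
#'
#' @param rate Numeric vector of response rates in `[0, 1]`; `NA` (no
#'   messages received) maps to `none`.
#' @param bins A [level_binning()].
#' @return A factor with levels `none < low < medium < high`.
#' @export
assign_level <- function(rate, bins = level_binning()) {
  stopifnot(inherits(bins, "level_binning"))
  if (any(!is.na(rate) & (rate < 0 | rate > 1))) {
    abort("response rates must lie in [0, 1]", class = "engagerx_validation_error")
  }
  out <- dplyr::case_when(
    is.na(rate) | rate == 0 ~ "none",
    rate <= bins$cut_low ~ "low",
    rate <= bins$cut_mid ~ "medium",
    .default = "high"
  )
  factor(out, levels = level_labels)
}

#' Per-user engagement profiles
#'
#' Combines response counts and rate, the engagement level, response flags
#' for the first and last message received, the unsubscribe flag, and
#' 30-day monthly response rates (months counted from each user's own
#' enrollment date). Baseline users with no events are retained with
#' `n_received = 0` and level `none`.
#'
#' @param events Validated event log.
#' @param baseline Validated baseline table.
#' @param bins A [level_binning()].
#' @param n_months Number of 30-day windows to summarise (default 6).
#' @return A tibble with one row per baseline user: `user_id`,
#'   `n_received`, `n_rated`, `response_rate`, `level`, `responded_first`,
#'   `responded_last`, `unsubscribed`, and `month_rate_1` ...
#'   `month_rate_<n_months>` (`NA` for months with no sends).
#' @export
engagement_profiles <- function(events, baseline, bins = level_binning(),
                                n_months = 6L) {
  events <- validate_events(events)
  baseline <- validate_baseline(baseline)
  rates <- response_rates(events)
  flags <- events |>
    summarise(
      responded_first = !is.na(.data$rating[which.min(.data$seq)]),
      responded_last = !is.na(.data$rating[which.max(.data$seq)]),
      .by = "user_id"
    )
  monthly <- monthly_user_rates(events, baseline, n_months = n_months) |>
    mutate(month = paste0("month_rate_", .data$month)) |>
    tidyr::pivot_wider(id_cols = "user_id", names_from = "month",
                       values_from = "rate")
  baseline |>
    select("user_id", "unsubscribed") |>
    left_join(rates, by = "user_id") |>
    left_join(flags, by = "user_id") |>
    left_join(monthly, by = "user_id") |>
    mutate(
      n_received = tidyr::replace_na(.data$n_received, 0L),
      n_rated = tidyr::replace_na(.data$n_rated, 0L),
      responded_first = tidyr::replace_na(.data$responded_first, FALSE),
      responded_last = tidyr::replace_na(.data$responded_last, FALSE),
      level = assign_level(.data$response_rate, bins)
    ) |>
    select("user_id", "n_received", "n_rated", "response_rate", "level",
           "responded_first", "responded_last", "unsubscribed",
           dplyr::starts_with("month_rate_"))
}

# Per-user monthly response rates. Month m covers days [30(m-1), 30m)
# after the user's own enrollment; sends beyond n_months windows are
# assigned to the last window.
monthly_user_rates <- function(events, baseline, n_months = 6L) {
  events |>
    left_join(select(baseline, "user_id", "enrolled_at"), by = "user_id") |>
    mutate(
      month = pmin(
        as.integer(as.numeric(.data$sent_at - .data$enrolled_at) %/% 30) + 1L,
        n_months
      )
    ) |>
    summarise(
      n_sent = dplyr::n(),
      n_rated = sum(!is.na(.data$rating)),
      rate = .data$n_rated / .data$n_sent,
      .by = c("user_id", "month")
    )
}

#' Monthly engagement trend, stratified by overall level
#'
#' Splits the follow-up into 30-day windows from each user's enrollment and
#' computes, per window and per overall engagement stratum (`low`,
#' `medium`, `high`; zero-responders have no monthly signal and are
#' omitted), two population metrics: the mean of the per-user monthly
#' response rates, and the percent of users with zero responses that month.
#' Users with no sends in a window are excluded from that window's
#' denominators.
#'
#' @inheritParams engagement_profiles
#' @return A tibble of class `engagement_trend` with columns `level`,
#'   `month`, `n_users`, `mean_rate`, `pct_zero`.
#' @export
trend_metrics <- function(events, baseline, bins = level_binning(),
                          n_months = 6L) {
  events <- validate_events(events)
  baseline <- validate_baseline(baseline)
  overall <- response_rates(events) |>
    mutate(level = assign_level(.data$response_rate, bins)) |>
    select("user_id", "level")
  out <- monthly_user_rates(events, baseline, n_months = n_months) |>
    left_join(overall, by = "user_id") |>
    filter(.data$level %in% c("low", "medium", "high")) |>
    summarise(
      n_users = dplyr::n(),
      mean_rate = mean(.data$rate),
      pct_zero = mean(.data$rate == 0),
      .by = c("level", "month")
    ) |>
    mutate(level = factor(.data$level, levels = c("low", "medium", "high"))) |>
    arrange(.data$level, .data$month)
  class(out) <- c("engagement_trend", class(out))
  out
}

#' Cohort-level engagement summary
#'
#' A compact long-format summary of engagement with the messaging system:
#' overall mean (SD) response rate, user counts per engagement level, and
#' counts of users who did not respond to the first / last message or who
#' unsubscribed during follow-up.
#'
#' @param profiles Output of [engagement_profiles()].
#' @return A tibble with columns `measure`, `category`, `n`, `mean`, `sd`,
#'   `percent` (unused slots `NA`).
#' @export
summarise_engagement <- function(profiles) {
  n <- nrow(profiles)
  lev <- profiles |>
    count(.data$level, .drop = FALSE) |>
    mutate(
      measure = "level of response rate",
      category = as.character(.data$level),
      percent = 100 * .data$n / !!n,
      mean = NA_real_, sd = NA_real_
    ) |>
    select("measure", "category", "n", "mean", "sd", "percent")
  n_total <- n
  flag_row <- function(measure, x) {
    tibble(measure = measure, category = "yes", n = sum(x),
           mean = NA_real_, sd = NA_real_, percent = 100 * sum(x) / n_total)
  }
  dplyr::bind_rows(
    tibble(
      measure = "overall response rate", category = NA_character_,
      n = n, mean = mean(profiles$response_rate, na.rm = TRUE),
      sd = sd(profiles$response_rate, na.rm = TRUE), percent = NA_real_
    ),
    tibble(
      measure = "messages received per user", category = NA_character_,
      n = n, mean = mean(profiles$n_received),
      sd = sd(profiles$n_received), percent = NA_real_
    ),
    tibble(
      measure = "messages rated per user", category = NA_character_,
      n = n, mean = mean(profiles$n_rated),
      sd = sd(profiles$n_rated), percent = NA_real_
    ),
    lev,
    flag_row("did not respond to the first message", !profiles$responded_first),
    flag_row("did not respond to the last message", !profiles$responded_last),
    flag_row("unsubscribed from messages", profiles$unsubscribed)
  )
}
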