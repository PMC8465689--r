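# Perceived-influence metrics derived from message ratings: per-user mean
# rating and binning, percent of messages rated influential (rating > 3),
# the improvement-after-negative-feedback statistic, and the high-impact
# message ranking.

bin_rating <- function(mean_rating) {
  out <- dplyr::case_when(
    is.na(mean_rating) ~ "no_rating",
    mean_rating <= 3.0 ~ "low",
    mean_rating <= 4.0 ~ "moderate",
    mean_rating <= 4.5 ~ "good",
    .default = "excellent"
  )
  factor(out, levels = rating_bin_labels)
}

bin_influential <- function(pct) {
  out <- dplyr::case_when(
    is.na(pct) ~ "no_rating",
    pct < 0.5 ~ "<0.5",
    pct < 0.8 ~ "0.5-0.8",
    pct < 1.0 ~ "0.8-1.0",
    .default = "1.0"
  )
  factor(out, levels = influential_bin_labels)
}

bin_improvement <- function(frac) {
  out <- dplyr::case_when(
    is.na(frac) ~ "ineligible",
    frac < 0.5 ~ "<0.5",
    frac < 0.8 ~ "0.5-0.8",
    .default = ">=0.8"
  )
  factor(out, levels = improvement_bin_labels)
}

# Eligible pairs: (event rated <= 3, immediately next sent event), kept only
# when the next event is rated. Returns pair counts.
improvement_pairs <- function(ratings, message_ids = NULL,
                              exclude_resend_pairs = FALSE) {
  n <- length(ratings)
  if (n < 2) {
    return(list(n_pairs = 0L, n_improved = 0L))
  }
  cur <- ratings[-n]
  nxt <- ratings[-1]
  keep <- !is.na(cur) & cur <= 3 & !is.na(nxt)
  if (exclude_resend_pairs && !is.null(message_ids)) {
    keep <- keep & message_ids[-n] != message_ids[-1]
  }
  list(n_pairs = sum(keep), n_improved = sum(nxt[keep] > cur[keep]))
}

#' Improvement after negative feedback
#'
#' For one user's events in send order: among pairs formed by a low-rated
#' event (rating <= 3, i.e. "strongly disagree" to "neutral") and the
#' immediately next sent event, restricted to pairs whose next event was
#' rated, the fraction in which the next rating is strictly higher. A user
#' with no eligible pair is ineligible and gets `NA`.
#'
#' @param ratings Integer vector of ratings in send order (`NA` = unrated).
#' @param message_ids Optional character vector of message ids matching
#'   `ratings`; only needed with `exclude_resend_pairs = TRUE`.
#' @param exclude_resend_pairs If `TRUE`, drop pairs in which the next send
#'   is a re-send of the same message. Under the study protocol a rated
#'   message is always followed by a different message, so this flag only
#'   matters for event logs that deviate from the protocol.
#' @return The improvement fraction in `[0, 1]`, or `NA` if ineligible.
#' @export
#' @examples
#' improvement_after_negative(c(2, 4, 3, NA, 5, 1, 1, NA)) # 0.5
improvement_after_negative <- function(ratings, message_ids = NULL,
                                       exclude_resend_pairs = FALSE) {
  if (any(!is.na(ratings) & !(ratings %in% 1:5))) {
    abort("ratings must be NA or integers in 1-5",
          class = "engagerx_validation_error")
  }
  p <- improvement_pairs(ratings, message_ids, exclude_resend_pairs)
  if (p$n_pairs == 0) NA_real_ else p$n_improved / p$n_pairs
}

#' Per-user perceived-influence profiles
#'
#' For each user in the event log: the mean rating over rated messages and
#' its bin (<= 3.0 low; (3, 4] moderate; (4, 4.5] good; (4.5, 5]
#' excellent; `no_rating` when nothing was rated), the percent of rated
#' messages deemed influential (rating > 3, i.e. "agree" or "strongly
#' agree") and its bin, and the improvement-after-negative-feedback
#' fraction and its bin (`ineligible` when the user has no eligible pair).
#'
#' @param events Validated event log.
#' @param exclude_resend_pairs Passed to [improvement_after_negative()].
#' @return A tibble with one row per user: `user_id`, `n_rated`,
#'   `mean_rating`, `rating_bin`, `pct_influential`, `pct_influential_bin`,
#'   `improvement_frac`, `n_improvement_pairs`, `improvement_bin`.
#' @export
influence_profiles <- function(events, exclude_resend_pairs = FALSE) {
  events <- validate_events(events)
  events |>
    summarise(
      n_rated = sum(!is.na(.data$rating)),
      mean_rating = ifelse(.data$n_rated > 0,
                           mean(.data$rating, na.rm = TRUE), NA_real_),
      pct_influential = ifelse(.data$n_rated > 0,
                               mean(.data$rating[!is.na(.data$rating)] > 3),
                               NA_real_),
      improvement_frac = improvement_after_negative(
        .data$rating, .data$message_id, exclude_resend_pairs),
      n_improvement_pairs = improvement_pairs(
        .data$rating, .data$message_id, exclude_resend_pairs)$n_pairs,
      .by = "user_id"
    ) |>
    mutate(
      rating_bin = bin_rating(.data$mean_rating),
      pct_influential_bin = bin_influential(.data$pct_influential),
      improvement_bin = bin_improvement(.data$improvement_frac)
    ) |>
    select("user_id", "n_rated", "mean_rating", "rating_bin",
           "pct_influential", "pct_influential_bin", "improvement_frac",
           "n_improvement_pairs", "improvement_bin")
}

#' High-impact message ranking
#'
#' Ranks messages by the mean rating they received, restricted to messages
#' sent to at least `min_recipients` distinct users (a reliability floor
#' for the mean estimates). Ties are broken by number of ratings
#' (descending), then message id (ascending).
#'
#' @param events Validated event log.
#' @param min_recipients Minimum number of distinct recipients (default 20).
#' @param top_k Number of top messages to return (default 10; `Inf` for
#'   all eligible messages).
#' @return A tibble of at most `top_k` rows: `message_id`, `n_recipients`,
#'   `n_ratings`, `mean_rating`, ordered best first.
#' @export
message_impact <- function(events, min_recipients = 20, top_k = 10) {
  events <- validate_events(events)
  events |>
    summarise(
      n_recipients = dplyr::n_distinct(.data$user_id),
      n_ratings = sum(!is.na(.data$rating)),
      mean_rating = ifelse(.data$n_ratings > 0,
                           mean(.data$rating, na.rm = TRUE), NA_real_),
      .by = "message_id"
    ) |>
    filter(.data$n_recipients >= min_recipients, .data$n_ratings > 0) |>
    arrange(desc(.data$mean_rating), desc(.data$n_ratings), .data$message_id) |>
    head(n = top_k)
}

#' Cohort-level perceived-influence summary
#'
#' Long-format summary of the three rating-based measures: mean (SD) of the
#' per-user mean ratings among raters, and user counts per bin of mean
#' rating, percent-influential, and improvement-after-negative-feedback.
#' Percentages for the first two panels are over users who rated at least
#' one message; for the improvement panel, over eligible users.
#'
#' @param profiles Output of [influence_profiles()].
#' @return A tibble with columns `panel`, `category`, `n`, `mean`, `sd`,
#'   `percent`.
#' @export
summarise_influence <- function(profiles) {
  raters <- filter(profiles, .data$n_rated > 0)
  eligible <- filter(profiles, !is.na(.data$improvement_frac))
  bin_panel <- function(data, col, panel, drop_levels = character()) {
    data |>
      count(category = .data[[col]], .drop = FALSE) |>
      filter(!.data$category %in% drop_levels) |>
      mutate(
        panel = panel, category = as.character(.data$category),
        mean = NA_real_, sd = NA_real_,
        percent = 100 * .data$n / nrow(data)
      ) |>
      select("panel", "category", "n", "mean", "sd", "percent")
  }
  dplyr::bind_rows(
    tibble(
      panel = "mean rating score", category = NA_character_,
      n = nrow(raters), mean = mean(raters$mean_rating),
      sd = sd(raters$mean_rating), percent = NA_real_
    ),
    bin_panel(raters, "rating_bin", "level of mean rating score", "no_rating"),
    bin_panel(raters, "pct_influential_bin",
              "percent of messages rated influential", "no_rating"),
    bin_panel(eligible, "improvement_bin",
              "improvement after negative feedback", "ineligible")
  )
}
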