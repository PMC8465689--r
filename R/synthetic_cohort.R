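# Synthetic-cohort simulator. Emulates the messaging protocol of a
# feedback-seeking motivational-messaging intervention: messages sent every
# few days from a fixed pool over a 6-month follow-up, an unrated message
# re-sent at the next send, heterogeneous per-user response propensity with
# monthly decay, unsubscription, engagement-linked survey dropout, and a
# cessation outcome calibrated so that population-level odds ratios across
# realized engagement levels equal configured targets.

# Default demographic mix of the simulated population (marginal
# frequencies for a US national sample of adult smokers enrolling in a
# digital cessation program; education and pay-difficulty are missing for
# roughly a third of enrollees, reflecting partial baseline surveys).
default_demographics <- function() {
  list(
    age_group = c("19-24" = 59, "25-34" = 147, "35-44" = 137,
                  "45-54" = 120, "55-64" = 207, "65+" = 61),
    gender = c(female = 531, male = 200),
    african_american = c(yes = 97, no = 634),
    education = c("<=high school" = 140, "some college/technical" = 215,
                  "college graduate" = 141, "missing" = 235),
    pay_difficulty = c("very hard" = 93, "hard" = 75, "somewhat hard" = 163,
                       "not very hard" = 153, "don't know" = 13,
                       "missing" = 234),
    cigs_per_day = c("<=10" = 254, ">10&<=20" = 331, ">20" = 146)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults emulate the study
#' conditions of a 731-smoker, 6-month messaging cohort: one message every
#' 3 days from a 500-message pool, about 15.5% unsubscribing, a baseline
#' (zero-engagement) cessation probability of 12.5% under
#' missing-outcome-as-smoking coding, and cessation odds ratios of
#' 1.86 / 2.30 / 2.69 for the low / medium / high engagement levels
#' relative to non-response.
#'
#' @param n_users Cohort size (default 731).
#' @param followup_days Follow-up length in days (default 180).
#' @param send_interval_days Days between sends (default 3).
#' @param pool_size Number of distinct messages available (default 500).
#' @param p_never Probability a user is a structural never-responder
#'   (response propensity exactly 0; default 0.28).
#' @param propensity_shape Beta(a, b) shape parameters for the response
#'   propensity of potential responders (default `c(0.25, 0.25)`, a
#'   U-shaped mix of barely- and highly-engaged users).
#' @param monthly_decay Multiplicative decay of the response probability
#'   per 30-day window, in (0, 1] (default 0.88).
#' @param rating_mean,rating_sd_message Mean and SD of the latent
#'   per-message influence, truncated to `[1, 5]` (defaults 4.05, 0.35).
#' @param rating_sd_user SD of the per-user leniency offset (default 1.0).
#' @param rating_sd_noise SD of the per-event rating noise (default 0.6).
#' @param unsub_prob Probability of unsubscribing during follow-up
#'   (default 0.155), at a uniformly drawn day.
#' @param dropout_intercept,dropout_slope Logistic model for survey
#'   completion: `logit P(complete) = intercept + slope * propensity`
#'   (defaults `qlogis(0.294)` and 4.4, giving ~29% retention among
#'   never-responders and ~96% among the most engaged).
#' @param cessation_base Cessation probability (missing = smoking coding)
#'   for the non-response level (default 0.125).
#' @param cessation_or Target odds ratios for the low / medium / high
#'   engagement levels vs non-response (default `c(1.86, 2.30, 2.69)`).
#' @param age_propensity_shift Named or positional numeric vector (length
#'   6, one per age group) of logit shifts applied to the response
#'   propensity; default all 0. Use together with `age_cessation_shift` to
#'   induce confounding by age.
#' @param age_cessation_shift Log-odds shifts on cessation per age group;
#'   default all 0.
#' @param enrollment_start First possible enrollment date.
#' @param enrollment_days Width of the enrollment window in days.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_users = 731L,
                       followup_days = 180L,
                       send_interval_days = 3L,
                       pool_size = 500L,
                       p_never = 0.28,
                       propensity_shape = c(0.25, 0.25),
                       monthly_decay = 0.88,
                       rating_mean = 4.05,
                       rating_sd_message = 0.35,
                       rating_sd_user = 1.0,
                       rating_sd_noise = 0.6,
                       unsub_prob = 0.155,
                       dropout_intercept = qlogis(0.294),
                       dropout_slope = 4.4,
                       cessation_base = 0.125,
                       cessation_or = c(low = 1.86, medium = 2.30, high = 2.69),
                       age_propensity_shift = rep(0, 6),
                       age_cessation_shift = rep(0, 6),
                       enrollment_start = as.Date("2017-07-01"),
                       enrollment_days = 600L) {
  cfg <- list(
    n_users = as.integer(n_users),
    followup_days = as.integer(followup_days),
    send_interval_days = as.integer(send_interval_days),
    pool_size = as.integer(pool_size),
    p_never = p_never,
    propensity_shape = propensity_shape,
    monthly_decay = monthly_decay,
    rating_mean = rating_mean,
    rating_sd_message = rating_sd_message,
    rating_sd_user = rating_sd_user,
    rating_sd_noise = rating_sd_noise,
    unsub_prob = unsub_prob,
    dropout_intercept = dropout_intercept,
    dropout_slope = dropout_slope,
    cessation_base = cessation_base,
    cessation_or = setNames(as.numeric(cessation_or),
                            c("low", "medium", "high")),
    age_propensity_shift = setNames(as.numeric(age_propensity_shift), age_groups),
    age_cessation_shift = setNames(as.numeric(age_cessation_shift), age_groups),
    enrollment_start = as.Date(enrollment_start),
    enrollment_days = as.integer(enrollment_days)
  )
  with(cfg, {
    stopifnot(
      n_users >= 1, followup_days >= 1, send_interval_days >= 1,
      pool_size >= 1,
      p_never >= 0, p_never <= 1,
      length(propensity_shape) == 2, all(propensity_shape > 0),
      monthly_decay > 0, monthly_decay <= 1,
      rating_sd_message >= 0, rating_sd_user >= 0, rating_sd_noise >= 0,
      unsub_prob >= 0, unsub_prob <= 1,
      cessation_base > 0, cessation_base < 1,
      all(cessation_or > 0),
      length(age_propensity_shift) == 6, length(age_cessation_shift) == 6,
      enrollment_days >= 0
    )
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d users, %d days, send every %d days, pool %d\n",
    x$n_users, x$followup_days, x$send_interval_days, x$pool_size))
  cat(sprintf(
    "  propensity: %.2f never + Beta(%.2f, %.2f), decay %.2f/month\n",
    x$p_never, x$propensity_shape[1], x$propensity_shape[2], x$monthly_decay))
  cat(sprintf(
    "  cessation: base %.3f, OR %.2f/%.2f/%.2f (low/medium/high)\n",
    x$cessation_base, x$cessation_or[1], x$cessation_or[2], x$cessation_or[3]))
  invisible(x)
}

sample_categorical <- function(n, freqs) {
  labels <- names(freqs)
  out <- sample(labels, n, replace = TRUE, prob = freqs / sum(freqs))
  out[out == "missing"] <- NA_character_
  out
}

# Normal draw truncated to [lo, hi] via inverse-CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- runif(n, pnorm((lo - mean) / sd), pnorm((hi - mean) / sd))
  qnorm(u) * sd + mean
}

#' Simulate a synthetic messaging cohort
#'
#' Generates events, baseline, outcomes and the latent truth under the
#' protocol: each user receives a message every `send_interval_days` from
#' enrollment until `followup_days` or unsubscription; an unrated message
#' is re-sent at the next send (same message id, new `seq`); a rated
#' message is followed by a fresh message drawn uniformly without
#' replacement from the unsent pool. Each send is rated with probability
#' `propensity * monthly_decay^(month - 1)`; ratings are
#' `round(clamp(message_influence + user_leniency + noise, 1, 5))`.
#' Survey completion follows the dropout model on latent propensity, and
#' the cessation outcome is calibrated so that, under missing-outcome-as-
#' smoking coding, the population odds ratio of each realized engagement
#' level versus non-response equals `cessation_or`.
#'
#' Identical `config` and `seed` give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the single generator stream.
#' @return An object of class `sim_cohort`: list with tibbles `events`,
#'   `users`, `outcomes`, `truth` (per-user latents), `message_truth`
#'   (per-message latent influence), plus `config` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_users
  ids <- sprintf("u%05d", seq_len(n))

  demo <- default_demographics()
  users <- tibble(
    user_id = ids,
    age_group = sample_categorical(n, demo$age_group),
    gender = sample_categorical(n, demo$gender),
    african_american = sample_categorical(n, demo$african_american),
    education = sample_categorical(n, demo$education),
    pay_difficulty = sample_categorical(n, demo$pay_difficulty),
    cigs_per_day = sample_categorical(n, demo$cigs_per_day),
    enrolled_at = cfg$enrollment_start +
      sample.int(cfg$enrollment_days + 1L, n, replace = TRUE) - 1L
  )

  never <- runif(n) < cfg$p_never
  propensity <- ifelse(
    never, 0,
    rbeta(n, cfg$propensity_shape[1], cfg$propensity_shape[2])
  )
  shift <- unname(cfg$age_propensity_shift[users$age_group])
  propensity <- plogis(qlogis(propensity) + shift)
  propensity[never] <- 0 # qlogis(0) = -Inf survives the shift, made explicit
  leniency <- rnorm(n, 0, cfg$rating_sd_user)

  unsubscribed <- runif(n) < cfg$unsub_prob
  unsub_day <- ifelse(unsubscribed,
                      sample.int(cfg$followup_days, n, replace = TRUE),
                      NA_integer_)

  pool_ids <- sprintf("m%04d", seq_len(cfg$pool_size))
  message_truth <- tibble(
    message_id = pool_ids,
    influence = rtruncnorm(cfg$pool_size, cfg$rating_mean,
                           cfg$rating_sd_message, 1, 5)
  )

  per_user <- vector("list", n)
  for (i in seq_len(n)) {
    last_day <- if (unsubscribed[i]) {
      min(cfg$followup_days, unsub_day[i]) - 1L
    } else {
      cfg$followup_days - 1L
    }
    days <- seq.int(0L, last_day, by = cfg$send_interval_days)
    ns <- length(days)
    month <- days %/% 30L + 1L
    rated <- runif(ns) < propensity[i] * cfg$monthly_decay^(month - 1)
    # A fresh message is drawn at the start and after every rated send.
    msg_index <- 1L + c(0L, cumsum(rated[-ns]))
    n_distinct_msgs <- msg_index[ns]
    if (n_distinct_msgs > cfg$pool_size) {
      abort(sprintf(
        "message pool exhausted for user %s: %d distinct messages needed but pool_size = %d",
        ids[i], n_distinct_msgs, cfg$pool_size
      ), class = "engagerx_infeasible_config")
    }
    drawn <- sample.int(cfg$pool_size, n_distinct_msgs)
    msg <- drawn[msg_index]
    rating <- rep(NA_integer_, ns)
    if (any(rated)) {
      latent <- message_truth$influence[msg[rated]] + leniency[i] +
        rnorm(sum(rated), 0, cfg$rating_sd_noise)
      rating[rated] <- as.integer(pmin(pmax(round(latent), 1), 5))
    }
    per_user[[i]] <- list(days = days, msg = msg, rating = rating)
  }

  n_sends <- vapply(per_user, function(x) length(x$days), integer(1))
  events <- tibble(
    user_id = rep(ids, n_sends),
    message_id = pool_ids[unlist(lapply(per_user, `[[`, "msg"))],
    seq = unlist(lapply(n_sends, seq_len)),
    sent_at = rep(users$enrolled_at, n_sends) +
      unlist(lapply(per_user, `[[`, "days")),
    rating = unlist(lapply(per_user, `[[`, "rating"))
  )

  users <- users |>
    mutate(
      unsubscribed = unsubscribed,
      unsubscribed_at = .data$enrolled_at +
        ifelse(unsubscribed, unsub_day, NA_integer_)
    )

  n_rated <- vapply(per_user, function(x) sum(!is.na(x$rating)), integer(1))
  rate <- n_rated / n_sends
  level <- assign_level(rate, level_binning())
  log_or <- unname(c(none = 0, log(cfg$cessation_or))[as.character(level)])
  cess_shift <- unname(cfg$age_cessation_shift[users$age_group])
  target <- plogis(qlogis(cfg$cessation_base) + log_or + cess_shift)

  retention_prob <- plogis(cfg$dropout_intercept +
                             cfg$dropout_slope * propensity)
  completed <- runif(n) < retention_prob
  if (any(target > retention_prob)) {
    warn(paste0(
      "cessation target exceeds retention probability for ",
      sum(target > retention_prob),
      " user(s); their coded cessation rate is clamped at the retention rate"
    ))
  }
  # Calibration: P(completed & abstinent | user) = target, so the coded
  # (missing = smoking) success probability matches the configured level
  # odds ratios regardless of the dropout model.
  p_abst_given_completed <- pmin(target / retention_prob, 1)
  abstinent <- ifelse(completed,
                      runif(n) < p_abst_given_completed,
                      NA)

  outcomes <- tibble(
    user_id = ids,
    survey_completed = completed,
    abstinent_7day = abstinent
  )
  truth <- tibble(
    user_id = ids,
    never_responder = never,
    propensity = propensity,
    leniency = leniency,
    retention_prob = retention_prob,
    cessation_target = target,
    realized_rate = rate,
    realized_level = level
  )

  structure(
    list(events = validate_events(events),
         users = validate_baseline(users),
         outcomes = validate_outcomes(outcomes),
         truth = truth,
         message_truth = message_truth,
         config = cfg,
         seed = as.integer(seed)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> seed %d: %d users, %d events (%.1f%% rated), %d messages used\n",
    x$seed, nrow(x$users), nrow(x$events),
    100 * mean(!is.na(x$events$rating)),
    dplyr::n_distinct(x$events$message_id)
  ))
  invisible(x)
}

#' Write a simulated cohort as a CSV fixture set
#'
#' Writes `events.csv`, `baseline.csv`, `outcomes.csv` (readable by
#' [read_events()], [read_baseline()], [read_outcomes()]) plus the latent
#' `truth.csv` and `message_truth.csv` into a directory.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    baseline = file.path(dir, "baseline.csv"),
    outcomes = file.path(dir, "outcomes.csv"),
    truth = file.path(dir, "truth.csv"),
    message_truth = file.path(dir, "message_truth.csv")
  )
  write_events(sim$events, paths[["events"]])
  write_baseline(sim$users, paths[["baseline"]])
  write_outcomes(sim$outcomes, paths[["outcomes"]])
  write_table_csv(sim$truth, paths[["truth"]])
  write_table_csv(sim$message_truth, paths[["message_truth"]])
  invisible(paths)
}
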