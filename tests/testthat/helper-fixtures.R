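# In-code fixtures shared across test files.

# Build a valid event table for one or more users from rating vectors.
# ratings: named list user_id -> integer vector (NA = unrated).
make_events <- function(ratings, start = as.Date("2020-01-01"), interval = 3,
                        message_ids = NULL) {
  purrr::imap_dfr(ratings, function(r, uid) {
    n <- length(r)
    tibble::tibble(
      user_id = uid,
      message_id = if (is.null(message_ids)) sprintf("m%03d", seq_len(n))
                   else message_ids[[uid]],
      seq = seq_len(n),
      sent_at = start + interval * (seq_len(n) - 1),
      rating = as.integer(r)
    )
  })
}

# Minimal valid baseline rows for the given users.
make_baseline <- function(user_ids, enrolled_at = as.Date("2020-01-01"),
                          unsubscribed = FALSE) {
  n <- length(user_ids)
  tibble::tibble(
    user_id = user_ids,
    age_group = rep_len(c("25-34", "55-64"), n),
    gender = rep_len(c("female", "male"), n),
    african_american = rep_len(c("no", "yes"), n),
    education = rep_len(c("college graduate", NA), n),
    pay_difficulty = rep_len(c("hard", NA), n),
    cigs_per_day = rep_len(c("<=10", ">20"), n),
    enrolled_at = rep_len(enrolled_at, n),
    unsubscribed = rep_len(unsubscribed, n),
    unsubscribed_at = dplyr::if_else(rep_len(unsubscribed, n),
                                     rep_len(enrolled_at, n) + 30,
                                     as.Date(NA))
  )
}

make_outcomes <- function(user_ids, survey_completed = TRUE,
                          abstinent_7day = FALSE) {
  tibble::tibble(
    user_id = user_ids,
    survey_completed = rep_len(survey_completed, length(user_ids)),
    abstinent_7day = ifelse(rep_len(survey_completed, length(user_ids)),
                            rep_len(abstinent_7day, length(user_ids)), NA)
  )
}

# Default-condition simulation shared across test files (computed once).
sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(sim_cache$default)) {
    sim_cache$default <- simulate_cohort(sim_config(), seed = 101)
  }
  sim_cache$default
}

# A margin-constructed cohort jointly classified by response level and
# rating bin, with cessation events (missing outcome = smoking) whose
# marginal collapses match the reference incidence counts for both
# exposures: levels 35/279, 30/153, 41/151, 40/148 and rating bins 6/55,
# 28/138, 24/96, 53/163, 35/279. The joint cell allocation is a
# north-west-corner split consistent with both margins.
table4_margins_cohort <- function() {
  cells <- tibble::tribble(
    ~level,   ~rating_bin, ~n,  ~n_events,
    "none",   "no_rating", 279L, 35L,
    "low",    "low",        55L,  6L,
    "low",    "moderate",   98L, 24L,
    "medium", "moderate",   40L,  4L,
    "medium", "good",       96L, 24L,
    "medium", "excellent",  15L, 13L,
    "high",   "excellent", 148L, 40L
  )
  purrr::pmap_dfr(cells, function(level, rating_bin, n, n_events) {
    tibble::tibble(
      level = level, rating_bin = rating_bin,
      survey_completed = c(rep(TRUE, n_events), rep(FALSE, n - n_events)),
      abstinent_7day = c(rep(TRUE, n_events), rep(NA, n - n_events))
    )
  }) |>
    dplyr::mutate(
      level = factor(level, levels = c("none", "low", "medium", "high")),
      rating_bin = factor(rating_bin, levels = c("low", "moderate", "good",
                                                 "excellent", "no_rating"))
    )
}

# Expand a per-category count table into per-user rows for model fitting:
# `counts` is a tibble with columns category, n_events, n.
expand_counts <- function(counts, column) {
  purrr::pmap_dfr(counts, function(category, n_events, n) {
    tibble::tibble(
      !!column := category,
      survey_completed = c(rep(TRUE, n_events), rep(FALSE, n - n_events)),
      abstinent_7day = c(rep(TRUE, n_events), rep(NA, n - n_events))
    )
  })
}
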