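# Data model, validation, and delimited-text I/O for the three study tables:
# message-rating event logs, baseline characteristics, and cessation outcomes.
# All files are comma-separated UTF-8 with ISO-8601 dates; missing values are
# encoded as empty strings.

events_cols <- c("user_id", "message_id", "seq", "sent_at", "rating")
baseline_cols <- c(
  "user_id", "age_group", "gender", "african_american", "education",
  "pay_difficulty", "cigs_per_day", "enrolled_at", "unsubscribed",
  "unsubscribed_at"
)
outcomes_cols <- c("user_id", "survey_completed", "abstinent_7day")

read_schema_csv <- function(path, col_types, expected) {
  if (!file.exists(path)) {
    abort(paste0("File does not exist: ", path), class = "engagerx_io_error")
  }
  x <- readr::read_csv(path, col_types = col_types, na = "",
                       progress = FALSE, show_col_types = FALSE)
  if (!identical(names(x), expected)) {
    abort(
      paste0(
        "Header of ", basename(path), " must be exactly: ",
        paste(expected, collapse = ","), " (found: ",
        paste(names(x), collapse = ","), ")"
      ),
      class = "engagerx_schema_error"
    )
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(
      paste0("Malformed values in ", basename(path), ", first at row ",
             prob$row[1], ", column ", prob$col[1]),
      class = "engagerx_validation_error"
    )
  }
  x
}

#' Read and validate a message-event log
#'
#' One row per message sent to a user. `seq` gives the send order within a
#' user (consecutive integers starting at 1); `rating` is the 1-5 Likert
#' answer to the message-influence question ("strongly disagree" = 1 ...
#' "strongly agree" = 5), or missing when the user did not respond.
#'
#' @param path Path to a CSV file with columns
#'   `user_id,message_id,seq,sent_at,rating`. Missing ratings are empty
#'   strings; `sent_at` is an ISO-8601 date.
#' @return A tibble of events sorted by `(user_id, seq)` with columns
#'   `user_id` (character), `message_id` (character), `seq` (integer),
#'   `sent_at` (Date) and `rating` (integer or `NA`).
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "user_id,message_id,seq,sent_at,rating",
#'   "u1,m1,1,2020-01-01,4",
#'   "u1,m2,2,2020-01-04,"
#' ), path)
#' read_events(path)
read_events <- function(path) {
  x <- read_schema_csv(
    path,
    readr::cols(
      user_id = readr::col_character(),
      message_id = readr::col_character(),
      seq = readr::col_integer(),
      sent_at = readr::col_date(),
      rating = readr::col_integer()
    ),
    events_cols
  )
  validate_events(x)
}

#' Validate an in-memory event table
#'
#' Enforces the event-log invariants: ratings are missing or in 1-5, `seq`
#' runs 1,2,... within each user with no duplicates, and `sent_at` is
#' non-decreasing in `seq`.
#'
#' @param events A data frame with the event-log columns (see
#'   [read_events()]).
#' @return The validated events as a tibble sorted by `(user_id, seq)`.
#' @export
validate_events <- function(events) {
  x <- as_tibble(events)
  stopifnot(all(events_cols %in% names(x)))
  bad_rating <- which(!is.na(x$rating) & !(x$rating %in% 1:5))
  if (length(bad_rating) > 0) {
    abort(
      paste0("rating outside 1-5 at row ", bad_rating[1], " (user ",
             x$user_id[bad_rating[1]], ", seq ", x$seq[bad_rating[1]], ")"),
      class = "engagerx_validation_error"
    )
  }
  if (anyNA(x$user_id) || anyNA(x$seq) || anyNA(x$sent_at)) {
    abort("user_id, seq and sent_at must be non-missing in the event log",
          class = "engagerx_validation_error")
  }
  x <- arrange(x, .data$user_id, .data$seq)
  by_user <- x |>
    summarise(
      dup = anyDuplicated(.data$seq) > 0,
      consecutive = identical(as.integer(.data$seq), seq_len(length(.data$seq))),
      dates_ok = !is.unsorted(.data$sent_at),
      .by = "user_id"
    )
  if (any(by_user$dup)) {
    abort(paste0("duplicate (user_id, seq) for user ",
                 by_user$user_id[which(by_user$dup)[1]]),
          class = "engagerx_validation_error")
  }
  if (any(!by_user$consecutive)) {
    abort(paste0("seq not consecutive from 1 for user ",
                 by_user$user_id[which(!by_user$consecutive)[1]]),
          class = "engagerx_validation_error")
  }
  if (any(!by_user$dates_ok)) {
    abort(paste0("sent_at not monotone in seq for user ",
                 by_user$user_id[which(!by_user$dates_ok)[1]]),
          class = "engagerx_validation_error")
  }
  x
}

#' Read and validate a baseline-characteristics table
#'
#' @param path Path to a CSV file with columns
#'   `user_id,age_group,gender,african_american,education,pay_difficulty,cigs_per_day,enrolled_at,unsubscribed,unsubscribed_at`.
#'   `education` and `pay_difficulty` may be missing (empty); the other
#'   categorical fields must be non-missing and use the documented labels.
#' @return A tibble with one validated row per user.
#' @export
read_baseline <- function(path) {
  x <- read_schema_csv(
    path,
    readr::cols(
      user_id = readr::col_character(),
      age_group = readr::col_character(),
      gender = readr::col_character(),
      african_american = readr::col_character(),
      education = readr::col_character(),
      pay_difficulty = readr::col_character(),
      cigs_per_day = readr::col_character(),
      enrolled_at = readr::col_date(),
      unsubscribed = readr::col_logical(),
      unsubscribed_at = readr::col_date()
    ),
    baseline_cols
  )
  validate_baseline(x)
}

check_levels <- function(x, values, allowed, allow_na = FALSE) {
  ok <- values %in% allowed
  if (allow_na) ok <- ok | is.na(values)
  if (!all(ok)) {
    abort(
      paste0("invalid ", x, " value '", values[which(!ok)[1]],
             "'; allowed: ", paste(allowed, collapse = ", "),
             if (allow_na) " or missing"),
      class = "engagerx_validation_error"
    )
  }
  invisible(TRUE)
}

#' Validate an in-memory baseline table
#'
#' @param baseline A data frame with the baseline columns (see
#'   [read_baseline()]).
#' @return The validated baseline as a tibble.
#' @export
validate_baseline <- function(baseline) {
  x <- as_tibble(baseline)
  stopifnot(all(baseline_cols %in% names(x)))
  if (anyDuplicated(x$user_id) > 0) {
    abort(paste0("duplicated user_id in baseline: ",
                 x$user_id[anyDuplicated(x$user_id)]),
          class = "engagerx_validation_error")
  }
  if (anyNA(x$user_id) || anyNA(x$enrolled_at) || anyNA(x$unsubscribed)) {
    abort("user_id, enrolled_at and unsubscribed must be non-missing",
          class = "engagerx_validation_error")
  }
  check_levels("age_group", x$age_group, age_groups)
  check_levels("gender", x$gender, gender_groups)
  check_levels("african_american", x$african_american, yes_no)
  check_levels("education", x$education, education_groups, allow_na = TRUE)
  check_levels("pay_difficulty", x$pay_difficulty, pay_groups, allow_na = TRUE)
  check_levels("cigs_per_day", x$cigs_per_day, cigs_groups)
  bad_unsub <- xor(x$unsubscribed, !is.na(x$unsubscribed_at))
  if (any(bad_unsub)) {
    abort(paste0("unsubscribed_at must be present iff unsubscribed (user ",
                 x$user_id[which(bad_unsub)[1]], ")"),
          class = "engagerx_validation_error")
  }
  x
}

#' Read and validate a cessation-outcome table
#'
#' @param path Path to a CSV file with columns
#'   `user_id,survey_completed,abstinent_7day`. A missing `abstinent_7day`
#'   is only allowed when `survey_completed` is false (lost to follow-up).
#' @return A tibble with one validated row per user.
#' @export
read_outcomes <- function(path) {
  x <- read_schema_csv(
    path,
    readr::cols(
      user_id = readr::col_character(),
      survey_completed = readr::col_logical(),
      abstinent_7day = readr::col_logical()
    ),
    outcomes_cols
  )
  validate_outcomes(x)
}

#' Validate an in-memory outcome table
#'
#' @param outcomes A data frame with the outcome columns (see
#'   [read_outcomes()]).
#' @return The validated outcomes as a tibble.
#' @export
validate_outcomes <- function(outcomes) {
  x <- as_tibble(outcomes)
  stopifnot(all(outcomes_cols %in% names(x)))
  if (anyDuplicated(x$user_id) > 0) {
    abort("duplicated user_id in outcomes", class = "engagerx_validation_error")
  }
  if (anyNA(x$survey_completed)) {
    abort("survey_completed must be non-missing", class = "engagerx_validation_error")
  }
  bad <- x$survey_completed & is.na(x$abstinent_7day)
  if (any(bad)) {
    abort(paste0("abstinent_7day missing for survey completer ",
                 x$user_id[which(bad)[1]]),
          class = "engagerx_validation_error")
  }
  bad2 <- !x$survey_completed & !is.na(x$abstinent_7day)
  if (any(bad2)) {
    abort(paste0("abstinent_7day present for non-completer ",
                 x$user_id[which(bad2)[1]]),
          class = "engagerx_validation_error")
  }
  x
}

write_table_csv <- function(x, path) {
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write study tables to CSV
#'
#' Inverse of the corresponding readers; writes comma-separated UTF-8 with
#' ISO-8601 dates and empty strings for missing values, so that
#' read-write-read round-trips are bit-identical.
#'
#' @param events,baseline,outcomes Validated tables.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  write_table_csv(validate_events(events), path)
}

#' @rdname write_events
#' @export
write_baseline <- function(baseline, path) {
  write_table_csv(validate_baseline(baseline), path)
}

#' @rdname write_events
#' @export
write_outcomes <- function(outcomes, path) {
  write_table_csv(validate_outcomes(outcomes), path)
}

#' Join events, baseline and outcomes into a per-user cohort table
#'
#' Produces one row per baseline user with message counts attached. Users
#' with no events are retained with `n_received = 0`; users absent from the
#' outcome table are coded `survey_completed = FALSE` (dropout) with a
#' missing abstinence outcome.
#'
#' @param events Validated event log (may be empty).
#' @param users Validated baseline table; the authoritative user list.
#' @param outcomes Validated outcome table; may omit users.
#' @return A tibble with one row per baseline user: all baseline columns
#'   plus `n_received`, `n_rated`, `survey_completed`, `abstinent_7day`.
#' @export
join_cohort <- function(events, users, outcomes) {
  events <- validate_events(events)
  users <- validate_baseline(users)
  outcomes <- validate_outcomes(outcomes)
  orphan <- setdiff(unique(events$user_id), users$user_id)
  if (length(orphan) > 0) {
    abort(paste0("event user_id absent from baseline: ", orphan[1]),
          class = "engagerx_integrity_error")
  }
  counts <- events |>
    summarise(
      n_received = dplyr::n(),
      n_rated = sum(!is.na(.data$rating)),
      .by = "user_id"
    )
  users |>
    left_join(counts, by = "user_id") |>
    left_join(select(outcomes, dplyr::all_of(outcomes_cols)), by = "user_id") |>
    mutate(
      n_received = tidyr::replace_na(.data$n_received, 0L),
      n_rated = tidyr::replace_na(.data$n_rated, 0L),
      survey_completed = tidyr::replace_na(.data$survey_completed, FALSE)
    )
}
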