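# Reporting layer: cohort assembly, the four summary tables, figure data,
# rounding conventions, and the end-to-end pipeline with a reproducibility
# manifest.

#' Round half-up
#'
#' Decimal rounding in which a trailing 5 always rounds away from zero at
#' the given precision (the convention used for the reported tables, where
#' e.g. 2.5985 prints as 2.60); base R's `round()` rounds half to even.
#' Defined for non-negative values.
#'
#' @param x Non-negative numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(all(is.na(x) | x >= 0))
  floor(x * 10^digits + 0.5) / 10^digits
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), NA_character_,
         formatC(round_half_up(x, digits), format = "f", digits = digits))
}

fmt_or_ci <- function(est, lo, hi) {
  ifelse(is.na(est), "Reference",
         paste0(fmt_num(est, 2), " (", fmt_num(lo, 2), ", ",
                fmt_num(hi, 2), ")"))
}

fmt_incidence <- function(n_events, n) {
  paste0(n_events, "/", n, " (", fmt_num(100 * n_events / n, 1), ")")
}

#' Assemble the analysis cohort
#'
#' One row per baseline user joining message counts, outcome coding,
#' engagement level and perceived-influence metrics; the input to the
#' association analyses.
#'
#' @param events,baseline,outcomes Validated study tables.
#' @param bins A [level_binning()].
#' @return A tibble with baseline columns plus `n_received`, `n_rated`,
#'   `response_rate`, `level`, `responded_first`, `responded_last`,
#'   `mean_rating`, `rating_bin`, `pct_influential`, `improvement_frac`,
#'   `survey_completed`, `abstinent_7day`.
#' @export
build_cohort <- function(events, baseline, outcomes, bins = level_binning()) {
  eng <- engagement_profiles(events, baseline, bins = bins) |>
    select("user_id", "n_received", "n_rated", "response_rate", "level",
           "responded_first", "responded_last")
  infl <- influence_profiles(events) |>
    select("user_id", "mean_rating", "rating_bin", "pct_influential",
           "improvement_frac")
  join_cohort(events, baseline, outcomes) |>
    select(-dplyr::any_of(c("n_received", "n_rated"))) |>
    left_join(eng, by = "user_id") |>
    left_join(infl, by = "user_id") |>
    mutate(rating_bin = forcats_replace_na(.data$rating_bin))
}

# Users with no events have no influence profile row; they belong in the
# no_rating bin like users who received messages but rated none.
forcats_replace_na <- function(f) {
  f <- factor(as.character(f), levels = rating_bin_labels)
  f[is.na(f)] <- "no_rating"
  f
}

#' Baseline characteristics by engagement level
#'
#' Long-format contingency summary of each baseline factor across the four
#' engagement levels, with column percentages and a Pearson chi-square
#' homogeneity P value per factor (missing categories dropped before
#' testing).
#'
#' @param cohort Output of [build_cohort()].
#' @return A tibble: `variable`, `category`, `level`, `n`, `pct`,
#'   `p_value` (repeated within variable).
#' @export
render_table1 <- function(cohort) {
  vars <- c("age_group", "gender", "african_american", "education",
            "pay_difficulty", "cigs_per_day")
  purrr::map_dfr(vars, function(v) {
    d <- cohort |>
      filter(!is.na(.data[[v]])) |>
      count(category = .data[[v]], level = .data$level)
    tab <- d |>
      tidyr::pivot_wider(names_from = "level", values_from = "n",
                         values_fill = 0L)
    m <- as.matrix(tab[, -1])
    p <- chi_square_homogeneity(m)$p_value
    d |>
      mutate(
        variable = v,
        pct = 100 * .data$n / sum(.data$n),
        p_value = p,
        .by = "level"
      ) |>
      select("variable", "category", "level", "n", "pct", "p_value")
  })
}

#' Cessation by engagement: incidence and odds ratios
#'
#' Builds the association table for the two engagement exposures
#' (response-rate level and mean-rating bin): incidence of cessation
#' (missing outcome = smoking) as `events/N (%)`, plus unadjusted and
#' covariate-adjusted odds ratios with 95% CIs and P values. Reference
#' categories carry `"Reference"` in the formatted columns. ORs are
#' rounded half-up to 2 decimals and percentages to 1 decimal in the
#' formatted columns; unrounded values are kept in numeric columns.
#'
#' @param cohort Output of [build_cohort()].
#' @param adjusted Also fit the covariate-adjusted models (default `TRUE`;
#'   set `FALSE` when the cohort lacks covariate variation, leaving the
#'   adjusted columns `NA`).
#' @return A tibble: `exposure`, `category`, `n_events`, `n`, `incidence`,
#'   `or_unadjusted`, `p_unadjusted`, `or_adjusted`, `p_adjusted`, and
#'   numeric columns `or_unadj`, `or_adj`.
#' @export
render_table4 <- function(cohort, adjusted = TRUE) {
  purrr::map_dfr(c("level", "rating_bin"), function(expo) {
    unadj <- fit_cessation_model(cohort, exposure = expo, adjusted = FALSE)
    eu <- exposure_effects(unadj)
    blank <- mutate(eu, estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_)
    ea <- if (adjusted) {
      # separation / non-convergence in the adjusted model is reported
      # loudly but leaves the unadjusted columns usable
      tryCatch(
        exposure_effects(fit_cessation_model(cohort, exposure = expo,
                                             adjusted = TRUE)),
        engagerx_separation_error = function(e) {
          warn(paste0("adjusted model for exposure '", expo,
                      "' not estimable: ", conditionMessage(e)))
          blank
        },
        engagerx_convergence_error = function(e) {
          warn(paste0("adjusted model for exposure '", expo,
                      "' did not converge: ", conditionMessage(e)))
          blank
        }
      )
    } else {
      blank
    }
    quit <- code_cessation(cohort)
    inc <- cohort |>
      mutate(.quit = quit) |>
      summarise(n_events = sum(.data$.quit), n = dplyr::n(),
                .by = dplyr::all_of(expo)) |>
      rename(category = dplyr::all_of(expo)) |>
      mutate(category = as.character(.data$category))
    eu |>
      mutate(category = .data$category) |>
      left_join(inc, by = "category") |>
      left_join(
        select(ea, "category", or_adj = "estimate", adj_lo = "ci_low",
               adj_hi = "ci_high", adj_p = "p_value"),
        by = "category"
      ) |>
      transmute(
        exposure = expo,
        category = .data$category,
        n_events = .data$n_events,
        n = .data$n,
        incidence = fmt_incidence(.data$n_events, .data$n),
        or_unadj = .data$estimate,
        or_unadjusted = fmt_or_ci(.data$estimate, .data$ci_low, .data$ci_high),
        p_unadjusted = .data$p_value,
        or_adj = .data$or_adj,
        or_adjusted = dplyr::case_when(
          .data$reference ~ "Reference",
          is.na(.data$or_adj) ~ NA_character_,
          .default = fmt_or_ci(.data$or_adj, .data$adj_lo, .data$adj_hi)
        ),
        p_adjusted = .data$adj_p
      )
  })
}

#' Figure data: retention by engagement group
#'
#' Retention rates across response-rate levels and across mean-rating
#' bins, each with its Cochran-Armitage trend test.
#'
#' @param cohort Output of [build_cohort()].
#' @return A tibble: `grouping`, `category`, `n`, `n_completed`,
#'   `retention`, `trend_z`, `trend_p` (trend values repeated within
#'   grouping).
#' @export
retention_figure_data <- function(cohort) {
  blocks <- list(
    level = retention_by_level(cohort, "level"),
    rating_bin = retention_by_level(cohort, "rating_bin")
  )
  purrr::imap_dfr(blocks, function(res, nm) {
    res$rates |>
      rename(category = dplyr::all_of(nm)) |>
      mutate(
        grouping = nm, category = as.character(.data$category),
        trend_z = res$trend$statistic, trend_p = res$trend$p_value
      ) |>
      select("grouping", "category", "n", "n_completed", "retention",
             "trend_z", "trend_p")
  })
}

#' Figure data: response rate by rating bin
#'
#' Mean response rate per mean-rating bin, with a chi-square test of the
#' level-by-bin cross-tabulation (the two engagement measures are related
#' but not linearly).
#'
#' @param cohort Output of [build_cohort()].
#' @return A tibble: `rating_bin`, `n`, `mean_response_rate`, `p_crosstab`
#'   (repeated).
#' @export
response_by_rating_figure_data <- function(cohort) {
  tab <- cohort |>
    count(.data$level, .data$rating_bin) |>
    tidyr::pivot_wider(names_from = "rating_bin", values_from = "n",
                       values_fill = 0L)
  m <- as.matrix(tab[, -1])
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  p <- chi_square_homogeneity(m)$p_value
  cohort |>
    summarise(
      n = dplyr::n(),
      mean_response_rate = mean(.data$response_rate, na.rm = TRUE),
      .by = "rating_bin"
    ) |>
    arrange(.data$rating_bin) |>
    mutate(p_crosstab = p)
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> engagement and influence metrics ->
#' association analyses, writing every output as CSV plus a plain-text run
#' manifest. With the same config, seed and inputs, the data outputs are
#' byte-identical across runs (the manifest differs only in its
#' timestamp).
#'
#' Outputs written to `out_dir`: `engagement.csv`, `influence.csv`,
#' `messages_top.csv`, `table1.csv`, `table2.csv`, `table3.csv`,
#' `table4.csv`, `fig1.csv` (monthly trend), `fig2.csv` (retention),
#' `fig3.csv` (response rate by rating bin), `manifest.txt`, and — when
#' simulating — the fixture CSVs under `input/`.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_dir Directory containing `events.csv`, `baseline.csv`,
#'   `outcomes.csv`; `NULL` (default) simulates instead.
#' @param config A [sim_config()] used when simulating.
#' @param seed Seed for the simulation stream.
#' @param bins `"fixed"` (cutoffs 0.1 / 0.6) or `"data_driven"`
#'   (re-derived tertile cutoffs), or a [level_binning()].
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL, config = sim_config(),
                         seed = 1L, bins = "fixed") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "engagerx_pipeline_error", parent = e)
    })
  }

  if (is.null(input_dir)) {
    sim <- stage("simulate", simulate_cohort(config, seed = seed))
    input_dir <- file.path(out_dir, "input")
    stage("write_fixture", write_fixture(sim, input_dir))
    events <- sim$events; baseline <- sim$users; outcomes <- sim$outcomes
  } else {
    events <- stage("read_events",
                    read_events(file.path(input_dir, "events.csv")))
    baseline <- stage("read_baseline",
                      read_baseline(file.path(input_dir, "baseline.csv")))
    outcomes <- stage("read_outcomes",
                      read_outcomes(file.path(input_dir, "outcomes.csv")))
  }

  binning <- if (inherits(bins, "level_binning")) {
    bins
  } else if (identical(bins, "data_driven")) {
    rr <- response_rates(events)
    stage("derive_cutoffs",
          derive_cutoffs(rr$response_rate[!is.na(rr$response_rate) &
                                            rr$response_rate > 0]))
  } else {
    level_binning()
  }

  eng <- stage("engagement_metrics",
               engagement_profiles(events, baseline, bins = binning))
  infl <- stage("influence_metrics", influence_profiles(events))
  trend <- stage("trend_metrics",
                 trend_metrics(events, baseline, bins = binning))
  top <- stage("message_impact", message_impact(events))
  cohort <- stage("build_cohort",
                  build_cohort(events, baseline, outcomes, bins = binning))

  outputs <- list(
    engagement = eng,
    influence = infl,
    messages_top = top,
    table1 = stage("table1", render_table1(cohort)),
    table2 = stage("table2", summarise_engagement(eng)),
    table3 = stage("table3", summarise_influence(infl)),
    table4 = stage("table4", render_table4(cohort)),
    fig1 = trend,
    fig2 = stage("fig2", retention_figure_data(cohort)),
    fig3 = stage("fig3", response_by_rating_figure_data(cohort))
  )
  paths <- purrr::imap(outputs, function(x, nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_table_csv(as_tibble(x), p)
    p
  })

  manifest <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("package_version: ", as.character(utils::packageVersion("engagerx"))),
    paste0("seed: ", seed),
    paste0("config_hash: ", rlang::hash(config)),
    paste0("bins: ", sprintf("%.1f,%.1f,%s", binning$cut_low,
                             binning$cut_mid, binning$derivation)),
    paste0("input_events_hash: ", rlang::hash(events)),
    paste0("input_baseline_hash: ", rlang::hash(baseline)),
    paste0("input_outcomes_hash: ", rlang::hash(outcomes)),
    paste0("n_users: ", nrow(baseline)),
    paste0("n_events: ", nrow(events))
  )
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(c(paths, list(manifest = manifest_path)))
}
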