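test_that("odds ratio and Woolf interval match hand-computed values", {
  o <- odds_ratio_2x2(30, 123, 35, 244)
  expect_equal(o$estimate, (30 * 244) / (123 * 35), tolerance = 1e-12)
  se <- sqrt(1 / 30 + 1 / 123 + 1 / 35 + 1 / 244)
  expect_equal(o$ci_low, exp(log(o$estimate) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(o$ci_high, exp(log(o$estimate) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_identical(odds_ratio_2x2(1, 1, 1, 1)$estimate, 1)
  expect_error(odds_ratio_2x2(0, 5, 3, 7), class = "engagerx_zero_cell_error")
  expect_error(odds_ratio_2x2(2.5, 5, 3, 7),
               class = "engagerx_validation_error")
})

test_that("Woolf interval contains the point estimate and narrows with larger cells", {
  withr::with_seed(1, {
    for (i in 1:25) {
      cells <- sample(1:50, 4, replace = TRUE)
      o <- do.call(odds_ratio_2x2, as.list(cells))
      expect_lte(o$ci_low, o$estimate)
      expect_gte(o$ci_high, o$estimate)
      wider <- do.call(odds_ratio_2x2, as.list(cells * 10))
      expect_lt(log(wider$ci_high / wider$ci_low),
                log(o$ci_high / o$ci_low))
    }
  })
})

test_that("chi-square equals the direct-formula oracle on random tables", {
  oracle <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  withr::with_seed(2, {
    for (i in 1:200) {
      r <- sample(2:4, 1); k <- sample(2:5, 1)
      tab <- matrix(sample(1:30, r * k, replace = TRUE), r, k)
      res <- chi_square_homogeneity(tab)
      expect_equal(res$statistic, oracle(tab), tolerance = 1e-10)
      expect_identical(res$df, as.integer((r - 1) * (k - 1)))
      expect_gte(res$p_value, 0)
      expect_lte(res$p_value, 1)
    }
  })
  # proportional rows carry no signal
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  res <- chi_square_homogeneity(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_error(chi_square_homogeneity(rbind(c(0, 0), c(1, 2))),
               class = "engagerx_zero_margin_error")
})

test_that("trend test: null flatness, k=2 Pearson identity, and direction", {
  flat <- cochran_armitage_trend(c(10, 20, 30), c(50, 100, 150))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1, tolerance = 1e-12)
  withr::with_seed(3, {
    for (i in 1:200) {
      n <- sample(10:60, 2, replace = TRUE)
      x <- vapply(n, function(m) sample.int(m - 1, 1), integer(1))
      ca <- cochran_armitage_trend(x, n)
      tab <- rbind(x, n - x)
      expect_equal(ca$statistic^2,
                   chi_square_homogeneity(tab)$statistic,
                   tolerance = 1e-8)
      # cross-check against the base implementation of the same test
      pt <- suppressWarnings(stats::prop.trend.test(x, n))
      expect_equal(ca$statistic^2, unname(pt$statistic), tolerance = 1e-8)
    }
  })
  inc <- cochran_armitage_trend(c(50, 150, 300), c(500, 500, 500))
  expect_gt(inc$statistic, 0)
  expect_lt(inc$p_value, 0.001)
})

test_that("ANOVA matches t-squared with two groups; Bonferroni never shrinks P", {
  two <- tibble::tibble(
    g = rep(c("a", "b"), each = 3),
    y = c(1, 2, 3, 1, 2, 3)
  )
  res <- anova_bonferroni(two, y, g)
  expect_equal(res$overall$statistic, 0, tolerance = 1e-12)
  expect_equal(res$overall$p_value, 1, tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:50) {
      d <- tibble::tibble(
        g = rep(c("a", "b"), times = c(8, 11)),
        y = rnorm(19, mean = rep(c(0, 0.8), times = c(8, 11)))
      )
      res <- anova_bonferroni(d, y, g)
      tt <- t.test(y ~ g, data = d, var.equal = TRUE)
      expect_equal(res$overall$statistic, unname(tt$statistic)^2,
                   tolerance = 1e-10)
      expect_equal(res$overall$p_value, tt$p.value, tolerance = 1e-10)
    }
    # multi-group: adjusted P >= raw P, capped at 1
    d3 <- tibble::tibble(
      g = rep(c("a", "b", "c", "d"), each = 12),
      y = rnorm(48, mean = rep(c(0, 0.1, 0.5, 1), each = 12))
    )
    res3 <- anova_bonferroni(d3, y, g)
    expect_identical(nrow(res3$pairwise), 6L)
    expect_true(all(res3$pairwise$p_adjusted >= res3$pairwise$p_value))
    expect_true(all(res3$pairwise$p_adjusted <= 1))
  })
  expect_error(anova_bonferroni(tibble::tibble(g = "a", y = 1), y, g),
               class = "engagerx_validation_error")
})

test_that("a raised 35-44 propensity shows up in the ANOVA pairwise contrast", {
  shift <- c(0, 0, 1.2, 0, 0, 0) # logit shift for the 35-44 group
  cfg <- sim_config(n_users = 2000, p_never = 0.2,
                    propensity_shape = c(2, 3),
                    age_propensity_shift = shift)
  sim <- simulate_cohort(cfg, seed = 41)
  d <- dplyr::left_join(response_rates(sim$events),
                        sim$users[, c("user_id", "age_group")], by = "user_id")
  res <- anova_bonferroni(d, response_rate, age_group)
  expect_lt(res$overall$p_value, 0.05)
  pair <- res$pairwise[(res$pairwise$group1 == "19-24" &
                          res$pairwise$group2 == "35-44") |
                         (res$pairwise$group1 == "35-44" &
                            res$pairwise$group2 == "19-24"), ]
  expect_lt(pair$p_adjusted, 0.05)
  diff_3544 <- ifelse(pair$group1 == "35-44", pair$mean_diff, -pair$mean_diff)
  expect_gt(diff_3544, 0)
})

test_that("retention rates and trend behave on constructed and simulated cohorts", {
  cohort <- tibble::tibble(
    level = factor(rep(c("none", "low", "medium", "high"), each = 8),
                   levels = c("none", "low", "medium", "high")),
    survey_completed = rep(TRUE, 32)
  )
  res <- retention_by_level(cohort, level)
  expect_true(all(res$rates$retention == 1))
  cohort$survey_completed[cohort$level == "none"] <- rep(c(TRUE, FALSE), 4)
  res2 <- retention_by_level(cohort, level)
  expect_equal(res2$rates$retention[res2$rates$level == "none"], 0.5)
  # simulated: retention monotone increasing in level
  sim <- simulate_cohort(sim_config(n_users = 3000), seed = 43)
  cohort3 <- build_cohort(sim$events, sim$users, sim$outcomes)
  res3 <- retention_by_level(cohort3, level)
  expect_true(all(diff(res3$rates$retention) > 0))
  expect_lt(res3$trend$p_value, 0.001)
  expect_gt(res3$trend$statistic, 0)
})

test_that("unadjusted logistic exposure effects equal cross-product odds ratios", {
  counts <- tibble::tibble(
    category = c("none", "low", "medium", "high"),
    n_events = c(35L, 30L, 41L, 40L),
    n = c(279L, 153L, 151L, 148L)
  )
  cohort <- expand_counts(counts, "level")
  fit <- fit_cessation_model(cohort, exposure = "level", adjusted = FALSE)
  eff <- exposure_effects(fit)
  for (lv in c("low", "medium", "high")) {
    a <- counts$n_events[counts$category == lv]
    n1 <- counts$n[counts$category == lv]
    o <- odds_ratio_2x2(a, n1 - a, 35, 244)
    got <- eff[eff$category == lv, ]
    expect_equal(got$estimate, o$estimate, tolerance = 1e-6)
    expect_equal(got$ci_low, o$ci_low, tolerance = 1e-4)
    expect_equal(got$ci_high, o$ci_high, tolerance = 1e-4)
  }
  expect_true(eff$reference[eff$category == "none"])
  expect_true(is.na(eff$estimate[eff$category == "none"]))
})

test_that("missing outcomes are coded as smoking and separation is reported", {
  cohort <- tibble::tibble(
    level = factor(rep(c("none", "low"), each = 20),
                   levels = c("none", "low")),
    survey_completed = rep(c(TRUE, FALSE), 20),
    abstinent_7day = ifelse(rep(c(TRUE, FALSE), 20), TRUE, NA)
  )
  fit <- fit_cessation_model(cohort, exposure = "level")
  expect_identical(fit$n_events, 20L) # only completer-abstainers count
  sep <- tibble::tibble(
    level = factor(rep(c("none", "low"), each = 10),
                   levels = c("none", "low")),
    survey_completed = TRUE,
    abstinent_7day = rep(c(FALSE, TRUE), each = 10)
  )
  expect_error(fit_cessation_model(sep, exposure = "level"),
               class = "engagerx_separation_error")
})

test_that("tidy and glance expose model results in broom form", {
  counts <- tibble::tibble(
    category = c("low", "moderate", "good", "excellent", "no_rating"),
    n_events = c(6L, 28L, 24L, 53L, 35L),
    n = c(55L, 138L, 96L, 163L, 279L)
  )
  cohort <- expand_counts(counts, "rating_bin")
  fit <- fit_cessation_model(cohort, exposure = "rating_bin")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value") %in% names(td)))
  expect_equal(
    td$estimate[td$term == "rating_bin:excellent"],
    odds_ratio_2x2(53, 110, 6, 49)$estimate,
    tolerance = 1e-6
  )
  gl <- glance(fit)
  expect_identical(gl$n, nrow(cohort))
  expect_true(gl$converged)
})

test_that("adjusted models recover configured effects under age confounding", {
  # ages shift both engagement and cessation, biasing the crude contrast;
  # adjustment for age restores the configured conditional odds ratios
  shift_p <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  shift_c <- c(-1.2, -0.8, -0.5, -0.3, -0.1, 0)
  cfg <- sim_config(n_users = 2000,
                    age_propensity_shift = shift_p,
                    age_cessation_shift = shift_c)
  target <- log(cfg$cessation_or)
  seeds <- 1:10
  covered <- 0
  bias_adj <- bias_unadj <- numeric(0)
  for (s in seeds) {
    sim <- simulate_cohort(cfg, seed = 1000 + s)
    cohort <- build_cohort(sim$events, sim$users, sim$outcomes)
    adj <- fit_cessation_model(cohort, exposure = "level", adjusted = TRUE,
                               covariates = "age_group")
    una <- fit_cessation_model(cohort, exposure = "level", adjusted = FALSE)
    ea <- exposure_effects(adj); eu <- exposure_effects(una)
    lv <- match(c("low", "medium", "high"), ea$category)
    inside <- log(ea$ci_low[lv]) <= target & target <= log(ea$ci_high[lv])
    covered <- covered + all(inside)
    bias_adj <- c(bias_adj, log(ea$estimate[lv]) - target)
    bias_unadj <- c(bias_unadj, log(eu$estimate[lv]) - target)
  }
  expect_gte(covered, 8)
  expect_lt(mean(abs(bias_adj)), mean(abs(bias_unadj)))
})
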