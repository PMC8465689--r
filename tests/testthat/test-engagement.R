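test_that("response rate is rated over received, with undefined distinct from zero", {
  ev <- make_events(list(
    u1 = c(rep(3L, 13), rep(NA, 46)),   # 13 of 59
    u2 = rep(NA, 40)                    # 0 of 40
  ))
  rr <- response_rates(ev)
  expect_equal(rr$response_rate[rr$user_id == "u1"], 13 / 59, tolerance = 1e-12)
  expect_equal(round(rr$response_rate[rr$user_id == "u1"], 4), 0.2203)
  expect_identical(rr$response_rate[rr$user_id == "u2"], 0)
  # user with zero events: undefined rate via the profile path
  bl <- make_baseline(c("u1", "u2", "u3"))
  prof <- engagement_profiles(ev, bl)
  expect_true(is.na(prof$response_rate[prof$user_id == "u3"]))
  expect_identical(prof$n_received[prof$user_id == "u3"], 0L)
})

test_that("derived cutoffs snap tertiles to the one-decimal grid", {
  # brute-force oracle: sort-and-interpolate quantile, then nearest grid
  # value with ties toward the lower one
  oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    q <- x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
    grid <- seq(0.1, 1, 0.1)
    grid[which(abs(grid - q) <= min(abs(grid - q)) + 1e-12)[1]]
  }
  rates <- c(0.05, 0.1, 0.2, 0.4, 0.5, 0.7, 0.8, 0.9, 1.0)
  bins <- derive_cutoffs(rates)
  expect_identical(bins$derivation, "data_driven")
  expect_equal(bins$cut_low, oracle(rates, 1 / 3))
  expect_equal(bins$cut_mid, oracle(rates, 2 / 3))

  withr::with_seed(42, {
    for (i in 1:50) {
      x <- runif(sample(5:60, 1), min = 0.01, max = 1)
      b <- tryCatch(derive_cutoffs(x), error = function(e) NULL)
      cl <- oracle(x, 1 / 3); cm <- oracle(x, 2 / 3)
      if (cl >= cm) {
        expect_null(b)
      } else {
        expect_equal(c(b$cut_low, b$cut_mid), c(cl, cm))
      }
    }
  })
})

test_that("rates whose tertiles sit near 0.08 and 0.62 yield the canonical 0.1 / 0.6 cutoffs", {
  # 9 values placing the type-7 tertiles at 0.08 and 0.62 exactly
  rates <- c(0.02, 0.05, 0.06, 0.09, 0.3, 0.6, 0.66, 0.8, 1.0)
  expect_equal(quantile(rates, c(1/3, 2/3), type = 7, names = FALSE),
               c(0.08, 0.62), tolerance = 1e-9)
  bins <- derive_cutoffs(rates)
  expect_equal(c(bins$cut_low, bins$cut_mid), c(0.1, 0.6))
})

test_that("degenerate rate distributions are rejected rather than binned", {
  expect_error(derive_cutoffs(rep(0.5, 10)),
               class = "engagerx_degenerate_binning")
  expect_error(derive_cutoffs(numeric(0)),
               class = "engagerx_degenerate_binning")
  expect_error(derive_cutoffs(c(0.2, 1.2)),
               class = "engagerx_validation_error")
})

test_that("level assignment uses closed right endpoints and maps undefined to none", {
  bins <- level_binning()
  expect_identical(
    as.character(assign_level(c(0, 0.05, 0.1, 0.35, 0.6, 0.8, 1, NA), bins)),
    c("none", "low", "low", "medium", "medium", "high", "high", "none")
  )
  expect_error(assign_level(1.5, bins), class = "engagerx_validation_error")
  # monotone: a higher rate never maps to a lower level
  r <- sort(runif(100))
  lv <- as.integer(assign_level(r, bins))
  expect_true(all(diff(lv) >= 0))
})

test_that("monthly trend handles early stoppers and saturated raters", {
  # u1: 10 sends/month for 6 months, rates 5 in month 1 only
  ratings_u1 <- c(c(5L, 5L, 5L, 5L, 5L, NA, NA, NA, NA, NA), rep(NA, 50))
  ev <- make_events(list(u1 = ratings_u1), interval = 3)
  bl <- make_baseline("u1")
  prof <- engagement_profiles(ev, bl)
  expect_equal(unlist(prof[1, paste0("month_rate_", 1:6)], use.names = FALSE),
               c(0.5, 0, 0, 0, 0, 0))
  tr <- trend_metrics(ev, bl)
  expect_equal(tr$pct_zero[tr$month >= 2], rep(1, 5))
  # all users rating everything: mean rate 1, zero-responder share 0
  ev2 <- make_events(list(a = rep(4L, 60), b = rep(5L, 60)))
  tr2 <- trend_metrics(ev2, make_baseline(c("a", "b")))
  expect_true(all(tr2$mean_rate == 1))
  expect_true(all(tr2$pct_zero == 0))
})

test_that("trend under strong decay declines within every stratum on simulated data", {
  sim <- simulate_cohort(sim_config(n_users = 2000, monthly_decay = 0.7),
                         seed = 31)
  tr <- trend_metrics(sim$events, sim$users)
  wide <- tidyr::pivot_wider(tr[, c("level", "month", "mean_rate")],
                             names_from = "month", values_from = "mean_rate")
  for (lv in wide$level) {
    row <- unlist(wide[wide$level == lv, as.character(1:6)])
    expect_true(all(diff(row) < 0.02))      # non-increasing up to MC noise
    expect_lt(row[6], row[1])
  }
})

test_that("levels partition the cohort and equal monthly exposure recovers the overall rate", {
  sim <- default_sim()
  prof <- engagement_profiles(sim$events, sim$users)
  expect_identical(sum(table(prof$level)), nrow(sim$users))
  # non-unsubscribing users send 10 messages every month: the unweighted
  # mean of monthly rates equals the overall response rate
  full <- prof[prof$n_received == 60, ]
  monthly <- as.matrix(full[, paste0("month_rate_", 1:6)])
  expect_equal(rowMeans(monthly), full$response_rate, tolerance = 1e-12)
  # summary percentages are over the whole cohort
  summ <- summarise_engagement(prof)
  first_row <- summ[summ$measure == "did not respond to the first message", ]
  expect_equal(first_row$percent, 100 * mean(!prof$responded_first),
               tolerance = 1e-12)
  lev_rows <- summ[summ$measure == "level of response rate", ]
  expect_equal(sum(lev_rows$percent), 100, tolerance = 1e-12)
})

test_that("first/last response flags follow seq order", {
  ev <- make_events(list(u1 = c(4L, NA, 2L), u2 = c(NA, 3L, NA)))
  prof <- engagement_profiles(ev, make_baseline(c("u1", "u2")))
  expect_identical(prof$responded_first, c(TRUE, FALSE))
  expect_identical(prof$responded_last, c(TRUE, FALSE))
})
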