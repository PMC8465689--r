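# engagerx

Engagement metrics and cessation outcomes for feedback-seeking
motivational-messaging interventions.

## What this is for

Digital smoking-cessation programs increasingly send motivational messages
that *ask for feedback*: each message carries a 5-point Likert question
("Does this message influence you to quit smoking?", 1 = strongly disagree
... 5 = strongly agree). The resulting event log — one row per message
sent, with an optional rating — captures user-system engagement at message
granularity. engagerx is for analysts of such interventions. It computes:

* **Behavioral engagement** — per-user response rate
  (messages rated / messages received), the four-level binning
  `none` (0), `low` (>0–0.1], `medium` (0.1–0.6], `high` (0.6–1] with
  data-driven tertile-derived cutoffs snapped to one decimal, first/last
  response flags, and monthly trend metrics over the 6-month follow-up;
* **Perceived influence** — per-user mean rating and bins, percent of
  messages rated influential (rating > 3), the
  improvement-after-negative-feedback statistic (fraction of low-rated
  messages, rating ≤ 3, whose *next rated* message scored strictly
  higher), and a high-impact message ranking (mean rating among messages
  sent to ≥ 20 users);
* **Association statistics** — 2×2 odds ratios with Woolf CIs
  (`exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`), Pearson chi-square
  homogeneity tests, the Cochran–Armitage trend test, one-way ANOVA with
  Bonferroni pairwise comparisons, retention by engagement level, and
  logistic regression of 7-day point prevalence abstinence on engagement
  under the conservative **missing outcome = smoking** coding
  (dropouts count as smokers), unadjusted or covariate-adjusted;
* **A synthetic-cohort simulator** emulating the messaging protocol (a
  message every 3 days from a 500-message pool, unrated messages re-sent,
  heterogeneous response propensity with monthly decay,
  engagement-linked dropout, configurable cessation odds ratios), so the
  entire pipeline runs and is testable with no participant data.

Everything takes and returns tibbles and composes with the pipe; fitted
models support `tidy()`/`glance()`, and result types have `autoplot()` /
`plot_*()` methods.

## Worked example

```r
library(engagerx)

sim  <- simulate_cohort(sim_config(), seed = 1)   # 731 users, 6 months
prof <- engagement_profiles(sim$events, sim$users)
summarise_engagement(prof)
#> # A tibble: 10 × 6
#>    measure                              category     n   mean     sd percent
#>  1 overall response rate                <NA>       731  0.301  0.328    NA
#>  2 messages received per user           <NA>       731 55.4   12.8      NA
#>  3 messages rated per user              <NA>       731 16.1   18.1      NA
#>  4 level of response rate               none       283 NA     NA        38.7
#>  5 level of response rate               low         80 NA     NA        10.9
#>  6 level of response rate               medium     157 NA     NA        21.5
#>  7 level of response rate               high       211 NA     NA        28.9
#>  8 did not respond to the first message yes        441 NA     NA        60.3
#>  9 did not respond to the last message  yes        580 NA     NA        79.3
#> 10 unsubscribed from messages           yes        110 NA     NA        15.0
```

About 39% of simulated users never rate a message, 55 messages arrive per
user on average (60 minus unsubscription), and 15% unsubscribe — the
heterogeneity these interventions actually show. Retention climbs steeply
with engagement, and abstinence follows:

```r
cohort <- build_cohort(sim$events, sim$users, sim$outcomes)
retention_by_level(cohort, level)
#> Retention by level
#>    level   n n_completed retention
#> 1   none 283          83 0.2932862
#> 2    low  80          26 0.3250000
#> 3 medium 157         122 0.7770701
#> 4   high 211         204 0.9668246
#> Cochran-Armitage trend: Z = 16.172, P = 7.941e-59

fit <- fit_cessation_model(cohort, exposure = "level", adjusted = TRUE)
fit
#> Logistic cessation model (missing outcome = smoking)
#>   exposure: level (reference none); adjusted for age_group,
#>   african_american, cigs_per_day, unsubscribed, n_received
#>   n = 731, events = 151
#>   category estimate ci_low ci_high  p_value reference
#> 1     none       NA     NA      NA       NA      TRUE
#> 2      low     1.31  0.676    2.54 0.422885     FALSE
#> 3   medium     2.36  1.455    3.84 0.000515     FALSE
#> 4     high     1.84  1.162    2.93 0.009479     FALSE
```

The odds ratios estimate, per engagement level versus non-response, the
multiplicative change in the odds of coded abstinence; at n = 731 a
single replicate is noisy around the configured truths (1.86 / 2.30 /
2.69), which is exactly what the parameter-recovery suite quantifies at
larger n. `run_pipeline(out_dir, config = sim_config(), seed = 1)` runs
simulate → metrics → associations end to end and writes every table and
figure dataset as CSV with a reproducibility manifest.

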