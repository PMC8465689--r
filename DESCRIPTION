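Package: engagerx
Title: Engagement Metrics and Cessation Outcomes for Feedback-Seeking
    Motivational Messaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify user-system engagement with feedback-seeking
    motivational-messaging interventions for smoking cessation and to relate
    engagement to retention and abstinence outcomes. Provides validated
    delimited-text I/O for message-rating event logs, per-user response-rate
    and perceived-influence metrics with data-driven level binning, monthly
    engagement trend summaries, contingency-table statistics (Woolf odds
    ratios, Pearson chi-square, Cochran-Armitage trend), one-way ANOVA with
    Bonferroni pairwise comparisons, logistic cessation models under
    missing-outcome-as-smoking coding, and a synthetic-cohort simulator that
    emulates an every-3-days messaging protocol with re-sending of unrated
    messages, heterogeneous response propensity, temporal decay,
    engagement-linked dropout, and calibrated cessation odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
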