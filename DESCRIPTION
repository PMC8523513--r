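Package: notifyrl
Title: Adaptive Notification Timing via Reinforcement Learning on a
    Behavioral Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven simulator of how a user responds to mobile-health
    notifications promoting a recurring target activity (running), built as a
    dynamic Bayesian network over latent memory accessibility, latent urge,
    and observable context, together with a notification-budget-restricted
    REINFORCE policy-gradient agent that learns when to send notifications.
    Includes maximum-likelihood fitting of factorized context distributions
    and their likelihood ratio, rule-based baseline agents, experiment
    runners with sliding-window learning curves, episode visualizations, and
    synthetic generators for activity logs and hourly weather streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
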