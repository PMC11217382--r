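Package: volpgg
Title: Voluntary Threshold Public Goods Games: Models, Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying collaboration as a threshold public goods
    game with an outside individual option. Implements the belief-based
    best-response model of the one-shot game (expected payoffs, best-response
    partitions, pivotal probabilities), population-level predictions under
    Beta-distributed beliefs (action shares, within-group cooperation rate,
    group success rate, normalized efficiency), a loner-externality model that
    interpolates between flexible and fixed group boundaries, a synthetic
    experiment generator emulating within-subject session designs with
    elicited beliefs-as-counts, finite-session group assignment and payoff
    realization with incentive bonuses, and the statistical pipeline used to
    analyse such experiments: condition summaries, participant-resampled
    bootstrap confidence intervals, random-intercept logistic regressions,
    and ROC comparison of belief-based predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    yaml,
    jsonlite,
    lme4,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
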