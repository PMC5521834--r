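Package: recallbb
Title: Hierarchical Beta-Binomial Analysis of Cued-Recall Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian estimation for 2x2 factorial paired-associate memory
    experiments crossing instruction style with study sequencing (massed
    versus spaced repetition). Per-participant recall counts are modelled
    with a hierarchical beta-binomial in the mode/concentration
    parameterization, estimated by a self-contained Metropolis-within-Gibbs
    sampler with conjugate participant-level updates. Posterior contrasts
    (main effects, interaction, difference of main effects) are summarized
    by kernel-density posterior modes and highest density intervals, on
    both recall accuracy and the concentration of attempted responses. A
    robust t-distributed two-group model handles rating-scale items, and a
    simulator generates complete synthetic experiments (study sequences,
    recall and attempt counts, ratings) so the full pipeline runs without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
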