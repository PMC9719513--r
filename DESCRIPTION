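Package: avoidance
Title: Behavioral and Neural Time-Series Analysis of Approach-Avoidance
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for rodent anxiety-like avoidance experiments
    combining behavioral tracking with neural recordings. Scores open-field
    and elevated plus-maze trajectories into zones and approach-retreat
    bouts, processes fiber-photometry fluorescence into trend-adjusted
    dF/F with context-specific baselines, aligns signals to behavioral
    events with nested (event-then-animal) averaging, classifies single
    units as excited or inhibited from peri-event time histogram Z-scores,
    and quantifies neural ensemble overlap with exact hypergeometric tests
    and catFISH convergence-rate statistics. Includes a synthetic-data
    generator with recorded ground truth (biased-random-walk trajectories,
    calcium-indicator kernel convolution with photobleaching, inhomogeneous
    Poisson spike trains, two-epoch Bernoulli activation labels) for
    validating every estimator against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
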