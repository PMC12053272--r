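Package: efbattery
Title: Adaptive Executive-Function Battery Simulation and Psychometric Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an adaptive, gamified battery of executive-function
    tasks and runs its psychometric validation pipeline at desk scale. The
    battery engine implements a closed-loop adaptive response-window
    staircase (10 ms down / 40 ms up with exponential streak scaling and
    tri-color trial feedback), eleven task paradigms (basic response time,
    forward/backward spatial span, flanker, two continuous performance
    tasks, Stroop, visual search, cueing, task switching, and a dual
    tap-and-trace task), and their scoring rules (rate correct score, mean
    correct response time, object span) with the full trial- and
    score-level cleaning cascade. A generative virtual-respondent cohort
    with a planted sparse partial-correlation structure feeds the
    validation analyses: test-retest intraclass correlations, pruned
    Gaussian graphical model estimation with full-information maximum
    likelihood, spinglass community detection, bootstrap edge stability,
    correlated three-factor and bifactor confirmatory models, multigroup
    network invariance, and concurrent-validity correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
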