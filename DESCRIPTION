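Package: pianoskill
Title: Scoring, Exercise Protocols and Rank-Based Analysis for Piano
    Motor-Sequence Learning Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies of explicit motor-sequence learning on the
    piano keyboard paired with acute cardiovascular exercise. Scores timed
    keypress performances against target melodies using order-preserving
    subsequence matching (pitch accuracy) and inter-onset-interval tolerance
    rules (rhythm accuracy); reads and writes Standard MIDI Files; computes
    graded-exercise-test outcomes (peak power output, VO2peak attainment) and
    builds personalized high- and low-intensity interval cycling protocols;
    simulates synthetic learner cohorts with group-dependent learning curves
    for end-to-end testing; and fits rank-based longitudinal mixed-effects
    models with Type III tests, containment degrees of freedom and
    least-squares contrasts, alongside the classical two-sample tests and
    power calculations used in such trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    nortest,
    Rcpp,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
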