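Package: fuzzneg
Title: Bilateral Automated Negotiation with Fuzzy Preferences and Genetic-Algorithm Opponent Modelling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates bilateral multi-issue automated negotiation under the
    alternating-offers protocol, aimed at doctor-patient shared decision-making
    over treatment plans. Preferences are expressed as trapezoidal fuzzy
    membership functions with per-issue importance weights; agents concede
    according to a multi-state strategy driven by the opponent's response, the
    agent's internal satisfaction, and time pressure, and may learn the hidden
    opposing preference profile with a genetic algorithm refined by
    concession-derived weights. Includes baseline agents (time-dependent and
    concession-only bidders, a complete-information oracle), a synthetic
    scenario generator emulating questionnaire-style preference data, outcome
    metrics (joint satisfaction, rounds, success rate), and an experiment
    harness for deadline/issue-count sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
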