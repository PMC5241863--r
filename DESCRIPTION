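Package: pdcoop
Title: Cooperation Dynamics in Finitely Repeated Prisoner's Dilemmas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the long-run dynamics of cooperation in
    finitely repeated Prisoner's Dilemma experiments. Provides a
    deterministic game engine over threshold (grim-retaliation) strategies,
    a smoothed fictitious play agent-based model with a planted fraction of
    resilient cooperators, inference of per-game strategies from behavioural
    play logs via consistency indicators and an exponentially weighted
    moving average, descriptive and inferential analytics (cooperation
    trajectories, restart effects, first-defection distributions,
    steady-state onset detection), and a seeded synthetic experiment
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
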