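Package: socialgaze
Title: Simulation and Parameter Estimation for Gaze-Contingent Social
    Interaction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of a virtual agent whose gaze behavior
    is organized as probabilistic macro states (initiating and responding to
    joint attention, object-oriented, partner-oriented and introspective
    attention) built from micro states with stochastic durations, Markov
    transitions and gaze-contingent triggers.  A synthetic participant
    module generates human-side gaze behavior (event streams and raw
    tracker-like samples), a parsing module turns samples into fixations
    and AOI dwell events (dispersion-based detection, data-quality
    exclusions), and an estimation module recovers the timing parameters
    (normal, log-normal and ex-Gaussian duration laws selected by BIC),
    AOI transition matrices, attention ratios and fixation heatmaps from
    the interaction logs, so the full closed loop runs and is testable
    without an eye tracker.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    fitdistrplus,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
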