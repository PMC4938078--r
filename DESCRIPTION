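Package: physbandit
Title: Two-Armed Bandit Decision Models for Physarum Foraging Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling exploration-exploitation decisions of the
    slime mould Physarum polycephalum on two-armed bandit arenas. Provides
    constructors for the experimental arena layouts (even, random and
    non-binary reward distributions on two 31-site arms), ten candidate
    behavioural decision rules expressed as stochastic move policies with a
    shared noise parameter, Gittins-index computation for Beta-Bernoulli
    bandits by the calibration method, a forward simulator of arm exploration
    with summary statistics (site-discovery difference curves and exact
    binomial tests of high-quality-arm choice), Bayesian model selection by
    marginal likelihood with the noise parameter integrated out, and a
    synthetic trajectory generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
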