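Package: patchforage
Title: Object-Inspection Foraging Models and Visual-Search Gaze Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reward-guided persistence in visual search
    through the lens of optimal foraging theory. Implements an
    object-inspection extension of the classic patch-leaving problem as a
    Markov decision process solved by dynamic programming with an iterative
    global-reward-rate fixed point, including information-restricted (POMDP)
    policies with Bayesian beliefs over the hidden environment. Also provides
    a behavioral analysis pipeline for eye-tracking sessions (velocity-based
    saccade detection, gaze-window decomposition of search time, ROC
    discriminability, permutation-tested rank correlations, bootstrap
    intervals, reward-rate ratios, and condition-variance decomposition) and
    a synthetic session generator with recorded ground truth for
    parameter-recovery testing.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
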