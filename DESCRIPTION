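Package: taprhythm
Title: Structural Predictors and Tapping Models for Complex Cyclic Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sensorimotor synchronization with complex
    cyclic rhythms. Enumerates the universe of nondegenerate well-formed
    rhythms (cyclic cue patterns with exactly two interonset-interval sizes
    distributed maximally evenly), computes rhythm-level structural
    predictors (evenness, balance, interval entropies, coherence and
    sameness quotients) and pulse-level predictors (Markov cue probabilities,
    derivative-of-Gaussian edge detection, projected centroid, autocorrelation
    phase matrix salience, sequential expectation, Povel accents), scores
    tapping performances (smoothed-indicator cosine accuracy, pulse-window tap
    assignment), simulates tapping cohorts with known ground truth, and fits
    the pulse-level observation families (binomial-logit tap probability,
    upper-censored normal velocity, two-sided truncated normal asynchrony,
    beta accuracy) with a signal-detection-style cue-interaction
    decomposition and VIF-guarded forward variable selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
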