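Package: valuefmri
Title: Synthetic Pipeline for Value-Guided Choice Behavior and Model-Based fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates macaque value-guided decision-making experiments and the
    analysis chain used to study value comparison signals in ventromedial
    prefrontal cortex. Provides generators for a "less-is-more" single/choice
    trial task and a three-option probabilistic reversal task, Rescorla-Wagner
    value learning with softmax choice and session-wise maximum-likelihood
    fitting, frequency-based subjective value estimation, forward models of
    ROI/voxel BOLD time series (a linear amplitude model and a two-pool
    attractor network) convolved with a macaque gamma hemodynamic response,
    a GLM engine with parametric value modulators and fixed-effects
    combination, decision-locked time-course epoching with leave-one-out peak
    selection, and the accompanying behavioral statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
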