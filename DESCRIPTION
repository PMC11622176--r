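Package: proactstriat
Title: Simulation and Analysis of Striatal Spike Trains and Oculomotor Choice Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse sequential-choice and fixation oculomotor
    experiments with simultaneously recorded striatal single units. Provides a
    synthetic session generator with known ground truth (task geometry, eye traces
    at 1 kHz, inhomogeneous-Poisson spike trains for good-preferring, bad-preferring
    and visual response archetypes), saccade detection and trial action
    classification (accept/return/stay/other/fixation break), behavioral statistics
    (Welch t tests, Fisher's exact test, action proportion tables), peristimulus
    time histograms, Gaussian spike density functions and baseline Z-scoring,
    k-means response typing with repeated-silhouette selection of K, a
    sliding-window divergence-onset statistic, reaction-time quartile correlation
    analysis, and linear mixed-model comparisons with a parametric-bootstrap
    likelihood-ratio test and Bonferroni-corrected pairwise post hocs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pbkrtest,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
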