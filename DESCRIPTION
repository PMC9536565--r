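Package: lettersim
Title: Reaction-Time Letter Similarity and Representational Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for measuring the perceptual similarity of letters from
    reaction-time experiments and comparing the resulting representational
    dissimilarity matrices (RDMs) against feature-space models. Includes
    counterbalanced design generators for odd-one-out visual search and
    speeded letter categorization, RT-to-RDM pipelines (within-session
    log/z normalisation for search, linear mixed-effects estimation for
    categorization), split-half noise ceilings with Spearman-Brown
    correction, model RDM conventions for pooled feature activations,
    letter-preferring feature-subspace selection, bootstrap comparison of
    model-behavior correlations over stimulus pairs, and a synthetic glyph
    and behavior simulator for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
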