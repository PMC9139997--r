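Package: skelmorph
Title: Skeleton-Based Shape Generation and Part-Structure Morphing for
    Animal/Plant Categorization Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates novel two-dimensional animal- and plant-like silhouettes
    from stochastic shape skeletons, manipulates their part structure (symmetry
    displacement of limb pairs, curvedness straightening, sprouting of
    second-order limbs), builds five-step animal-to-plant morph sequences, and
    reconstructs the stimulus designs of three two-alternative forced-choice and
    slider-rating experiments. Includes a cue-driven synthetic observer and the
    accompanying statistical battery (exact binomial preference tests, one-way
    ANOVA with Tukey post-hoc comparisons, one-sample t-tests, JZS Bayes
    factors, and maximum-likelihood psychometric function fits), plus JSON/SVG/
    PNG/CSV input-output for shapes, stimuli and response tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    png,
    polyclip,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
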