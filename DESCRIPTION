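Package: morphvision
Title: Receptor-Noise-Limited Visual Modelling of Color-Morph Discriminability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking whether visually guided predators can tell
    color morphs apart. Reads and preprocesses reflectance spectra
    (replicate averaging, negative-offset correction, instrument-artifact
    repair), reconstructs photoreceptor spectral sensitivities from
    lambda-max via the A1 visual-pigment template, computes quantum catches
    under ideal viewing conditions, and evaluates chromatic (Delta S) and
    achromatic (Delta L) contrasts in just-noticeable-difference units with
    the receptor-noise-limited model for six built-in predator visual
    systems (lizard, jumping spider, honey bee, house fly, starling,
    peafowl). Includes group-level comparison tables with discriminability
    calls, a ternary RGB chromaticity analysis of morph development across
    nymphal stages, and synthetic-data generators that emulate green/brown
    grasshopper reflectance and ontogenetic RGB clouds for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
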