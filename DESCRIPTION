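Package: phylorma
Title: Phylogenetic Reduced-Major-Axis Allometry of Cetacean Genital Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tree-aware reduced-major-axis (RMA) line fitting for allometric
    scaling studies, with Pagel's lambda estimated by maximum likelihood under
    a bivariate Brownian-motion model, isometry t-tests and confidence
    intervals on the scaling exponent, and likelihood-ratio tests of
    phylogenetic signal. Includes ingestion and cleaning of specimen-level
    cetacean vaginal morphometrics (fold-length thresholding and rounding
    rules, species means, log10 transformation), an end-to-end pipeline
    producing a three-regression scaling report (vaginal length vs body
    length, cumulative vaginal fold length vs body length, and the
    residual-on-residual regression), and a synthetic-data generator (Yule
    trees, correlated lambda-Brownian traits, specimen tables) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
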