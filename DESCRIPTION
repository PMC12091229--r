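Package: tenomech
Title: Nanoindentation Mechanics and Expression Analysis of Engineered
    Tendon Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for 3D tissue-engineered tendon
    constructs grown from adipose-derived stromal cells. Fits spherical
    (Hertzian) contact models to nanoindentation force-displacement curves
    to extract an effective Young's modulus over a 1 micron indentation
    window, computes stress-relaxation percentages from open-loop holds,
    quantifies relative gene expression by the 2^-ddCt method with
    reference-gene normalisation, 2-SD outlier exclusion and exact
    Mann-Whitney tests, and summarises construct geometry (diameters,
    cross-sections, volume fold change) and cell organisation (axis angles,
    regional densities). A seeded synthetic-data module simulates every
    input class, including standard-linear-solid relaxation with cantilever
    compliance, so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
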