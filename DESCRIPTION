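Package: tailmorph
Title: Morphometric Analysis for the Mouse-Tail Model of Psoriasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for the mouse-tail test, an in vivo
    morphometric assay of anti-psoriatic activity. Generates synthetic
    per-scale measurement tables and labeled pseudo-histology images with
    the hierarchical structure of a seven-arm topical-treatment study;
    extracts the primary measurements (granular-layer length, scale
    length, epidermal thickness) from label images; computes
    orthokeratosis degree, mean epidermal thickness and percentual drug
    activity; and reproduces the nonparametric statistical layer
    (Kruskal-Wallis omnibus and pairwise comparison matrices with exact
    permutation p-values).
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
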