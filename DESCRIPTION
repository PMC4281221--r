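Package: herdspot
Title: Detecting and Counting Large Mammals in Very-High-Resolution
    Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid pixel- and object-based classification pipeline for
    detecting and counting individual large mammals (wildebeest, zebra and
    similar-sized ungulates) in 0.5 m multispectral satellite imagery of
    open savannah.  Includes Gram-Schmidt pan-sharpening of 2 m
    multispectral imagery with a 0.5 m panchromatic band, Jeffries-Matusita
    spectral separability analysis, a backpropagation neural-network pixel
    classifier, multi-resolution region-merging segmentation with an
    object-based rule engine (landscape masking followed by animal
    refinement), detection accuracy metrics (count, omission and commission
    error with chi-square density-independence tests), and a seeded
    synthetic savannah scene generator so the whole pipeline is testable
    without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
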