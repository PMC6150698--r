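Package: cxscreen
Title: Optogenetic Functional-Connectivity Screening of the Drosophila Central Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for all-optical functional-connectivity screens of
    the Drosophila central complex: simulation of optogenetic-stimulation
    calcium-imaging screens with a planted ground-truth connectome, movie
    preprocessing (sub-pixel registration, k-means ROI segmentation, background
    and baseline estimation, dF/F0 extraction), the three-level
    repeat/run/pair response-statistic hierarchy, cell-type nomenclature
    parsing with an anatomical-overlap predicate, and connection inference by
    robust Mahalanobis distance to a null sample of anatomically
    non-overlapping pairs with a bootstrap significance threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
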