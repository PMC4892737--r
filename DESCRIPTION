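Package: phenopipe
Title: Template-Driven Plant Phenomics Image Processing and Trait Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A plant-phenomics toolkit that segments single-plant images taken
    against controlled backgrounds with a four-stage operator pipeline (crop,
    color-expression filtering, contour-area noise removal, contour-based
    cropping), extracts digital traits (raw image moments, dimensions,
    projected shoot area, convex-hull/density/growth-habit descriptors and
    color histograms), crawls image directory trees into an SQLite results
    database via path-pattern templates, executes per-image workflows as a
    dependency DAG with per-worker databases and a final aggregation step,
    and provides downstream statistics (adjusted genotype means, Pearson
    correlation, complete-linkage hierarchical clustering, one-way ANOVA).
    Includes a deterministic synthetic plant-image generator with exact
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    DBI,
    RSQLite,
    jsonlite,
    png,
    jpeg,
    ape,
    parallel,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    emmeans,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
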