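Package: peepr
Title: Personalized Expression Perturbation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-subject gene perturbation profiles ("barcodes") from
    case/control expression matrices by z-scoring each subject against the
    control reference, quantifies heterogeneity between subjects (Jaccard
    overlap, Fisher's exact overlap significance, z-profile correlation,
    gene-set enrichment), compiles a combinatorial pool of disease-associated
    genes using an analytic binomial occupancy null, and predicts disease
    status from the fraction of the pool present in a subject's profile via
    repeated stratified cross-validation, with a correlation-based k-nearest
    neighbour benchmark.  Includes a synthetic-data generator with planted
    disease modules and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
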