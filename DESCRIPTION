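Package: synclone
Title: Clonal Architecture of Synchronous Adenoma-Carcinoma Exome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired whole-exome somatic variant data from
    regionally synchronous colorectal adenoma and carcinoma lesions. Classifies
    somatic variants by regional clonality (clonal, adenoma-specific,
    carcinoma-specific), infers parallel versus stepwise tumor evolution by
    density-based clustering of paired mutant allele frequencies, calls
    microsatellite instability events from intraread repeat-length distributions
    with Kolmogorov-Smirnov tests under Benjamini-Hochberg FDR control, segments
    GC-corrected read-depth ratios with circular binary segmentation, and tests
    genes for class-specific mutation enrichment. Includes a synthetic-data
    generator that emits paired-lesion read counts under explicit clone models
    with recoverable ground truth, used to validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    igraph,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
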