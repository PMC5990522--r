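Package: clonetrace
Title: Clonal Architecture and Mutation-Order Inference from Targeted
    Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted single-cell amplicon sequencing of tumor
    samples, developed around T-cell acute lymphoblastic leukemia panels.
    Provides per-cell quality control based on locus and allelic drop-out at
    heterozygous germline SNPs, ternary genotype calling from allele depths,
    clonal deconvolution by hierarchical clustering on the Jaccard distance
    with error-aware refinement, consensus clone genotypes and frequencies,
    and a graph-based algorithm that enumerates candidate orders of mutation
    acquisition and scores them against the single-cell evidence under
    explicit false-present and false-absent rates. A synthetic-data
    generator with known clonal structure, acquisition order and noise
    provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
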