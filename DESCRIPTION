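Package: shotgunHLA
Title: HLA Class I Allele Prediction from Shotgun Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts HLA class I alleles (genes A, B and C) directly from
    shotgun sequencing reads (RNA-Seq, whole-genome or exome) without
    HLA-targeted amplification. Candidate reads are recruited by exact
    5' k-mer match against a reference allele database, assembled into
    depth-annotated contigs by greedy exact-overlap extension, and aligned
    reciprocally against the allele database; putative alleles are ranked
    by a coverage-and-identity score and annotated with a chance
    expect value and a log-scale confidence. Includes a read simulator,
    miniature allele-database generator and benchmark harness that measure
    sensitivity, specificity and ambiguity of the predictions at allele-group
    (two-digit) and protein-allele (four-digit) resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    Rsamtools,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
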