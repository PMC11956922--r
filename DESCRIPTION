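Package: sdparalog
Title: Paralog Identity, Gene Conversion and Regulatory Sharing in Segmental Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for high-identity segmental-duplication (SD) gene
    families, modeled on the human NOTCH2NL cluster on chromosome 1. Provides a
    synthetic cohort simulator with known truth (duplication times, substitutions,
    interlocus gene-conversion tracts, deletions, haplotype configurations), a
    k-mer anchored pairwise synteny engine with exact unit-cost alignment of
    inter-anchor gaps (longest-syntenic-block identity matrices, windowed identity
    profiles, indel extraction), duplicon-barcode construction and nearest-barcode
    locus assignment, a tripartite paralog-identity workflow (best transcript
    match, neighbor-joining clade, map location), interlocus gene-conversion
    calling with tract delineation, haplotype-configuration classification against
    an editable catalog with cohort summaries, strict-clock duplication dating
    calibrated on an outgroup split, and categorization of accessible chromatin
    elements shared across paralogs with percent-actuation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
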