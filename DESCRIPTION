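Package: minorlens
Title: Minor (U12-Type) Intron Annotation, Retention Quantification and
    Co-Evolution Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the minor (U12-dependent) spliceosome from
    RNA-seq style data: extraction of an intron catalog from a genome and
    transcript annotation; position-weight-matrix scoring of U12-type
    5' splice sites and branch points with classification of introns into
    minor A-type (AT-AN) and G-type (GT-AN/GC-AG) subtypes; counting of
    junction, boundary and intron-body reads from alignments and
    estimation of intron retention (psi); a replicate-aware beta-binomial
    likelihood-ratio test for differential retention with
    Benjamini-Hochberg correction, subtype-stratified summaries,
    cryptic-splice-site detection and hierarchical clustering; a
    phylogenetic-profile co-occurrence screen (phi coefficient) with
    hypergeometric term enrichment; and synthetic-data generators with
    known ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
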