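Package: hmwgs
Title: Structural Annotation and Evolutionary Grouping of HMW Glutenin
    Subunit Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Structural characterization of high-molecular-weight glutenin
    subunit (HMW-GS) genes from wheat and its wild relatives: open reading
    frame and pseudogene analysis (premature in-frame stop codons, tandem
    terminal stops, single-base-deletion frameshifts), segmentation of the
    translated subunit into signal peptide, N-terminal, central repetitive
    and C-terminal domains, lossless motif-grammar decomposition of the
    repetitive domain, x-type/y-type diagnostic classification, pairwise
    SNP/indel accounting between orthologous genes, and two-region
    neighbor-joining bootstrap phylogeny with clade-based group assignment.
    Includes a synthetic HMW-GS gene family generator with planted
    mutations and exact ground truth, so every stage of the pipeline can be
    tested without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ape,
    optparse,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
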