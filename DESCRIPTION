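Package: crtscan
Title: Profiling of Carotenogenesis (crt) Gene Clusters in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling carotenoid biosynthesis (crt) genotypes in
    annotated bacterial genomes, with an emphasis on the order
    Sphingomonadales. Implements orthologue calling by Smith-Waterman local
    protein alignment with Karlin-Altschul bit scores and E-values under
    composite acceptance criteria (identity, length difference, bit score,
    E-value); reconstruction of crt locus architecture including ORF
    overlaps and gaps diagnostic of translational coupling; diagnostic
    protein motif scanning; genotype-based strain grouping (groups I-IV)
    with colour and carotenoid prediction via reachability analysis over
    the carotenoid biosynthesis pathway; a synthetic annotated-genome
    generator with ground-truth manifests for end-to-end validation; and a
    curated 41-strain cohort table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
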