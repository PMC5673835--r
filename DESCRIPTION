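Package: ahepipe
Title: Anchored Hybrid Enrichment Locus Assembly and Supermatrix Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for anchored hybrid enrichment (AHE)
    target-capture data: probabilistic merging of overlapping read pairs,
    divergent reference assembly of probe-region loci with spaced k-mer
    seeding and flank extension, species-constrained orthology clustering
    from shared k-mer distances, conserved-site alignment masking and site
    trimming, and supermatrix concatenation with partition tables. Includes
    a ground-truthed simulator of anchor/flank loci, paired reads, gene
    duplications and cross-contamination so every stage can be validated
    against known truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
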