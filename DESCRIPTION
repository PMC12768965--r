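Package: bapscan
Title: Discovery and Classification of Lytic Phage Genomes in Bacterial Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for finding complete phage genomes hiding inside bacterial
    genome assemblies. Provides a feature-based gradient-boosted classifier
    that scores contigs for phage-likeness from overlapping gene-triplet
    feature vectors, a multi-rule classification cascade that assigns contigs
    to bacterial, plasmid, temperate-phage, lytic-phage or undetermined
    classes from length gates, reference-hit keywords and lifestyle marker
    genes, MinHash sketching with Mash-distance phage networks and ANI-style
    clustering, and length- and library-size-normalized phage-to-host
    abundance ratios. A seeded synthetic-genome generator with known ground
    truth makes the whole stack testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
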