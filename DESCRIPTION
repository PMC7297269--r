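Package: lncm6A
Title: Ensemble Random-Forest Prediction of N6-Methyladenosine Sites on
    Long Non-Coding RNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts N6-methyladenosine (m6A) modification sites on long
    non-coding RNA. Candidate adenosines under the DRACH consensus motif are
    encoded with 84 sequence-derived features (nucleotide chemical properties
    plus cumulative base frequencies over a 21-nt window) and 60 genomic
    features (transcript topology, splice-junction distances, motif identity,
    candidate clustering, evolutionary conservation, RNA secondary structure,
    annotation overlaps and gene-level z-scores). A random forest is trained
    separately on mRNA and lncRNA site sets and the two probability outputs
    are blended with a weighted ensemble whose weight is chosen by grid search
    on a validation split. Both full-transcript (intron-inclusive) and
    mature-RNA coordinate modes are supported, along with balanced dataset
    construction from replicate base-resolution site calls, ranked greedy
    feature selection under cross-validation, evaluation metrics, and a
    seeded synthetic-fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ranger,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
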