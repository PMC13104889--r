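Package: lncentropy
Title: Uncertainty-Aware Benchmarking of mRNA-lncRNA Coding-Potential Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for uncertainty-aware benchmarking of ensembles of
    mRNA/lncRNA coding-potential classifiers. Decomposes ensemble prediction
    uncertainty into predictive entropy and a mutual-information disagreement
    score, stratifies transcripts into low- and high-entropy groups by
    per-class percentile rules, and categorizes inter-tool agreement.
    Builds label-stable, redundancy-reduced benchmark cohorts with balanced
    cross-validation folds; extracts transcript-level repeat features from
    RepeatMasker output and non-B DNA motif features from interval calls;
    runs effect-size-based univariate enrichment (Vargha-Delaney A,
    Cramer's V) across uncertainty groups with feature clustering and
    representative selection; and derives global and per-transcript feature
    attributions from random-forest models via tree SHAP, computed in
    probability space. A seeded synthetic-cohort generator provides all
    inputs so the full analysis is reproducible without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    cluster,
    randomForest,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
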