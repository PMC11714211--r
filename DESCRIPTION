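Package: netrepurpose
Title: Network-Based Drug Repurposing Against a Seed-Gene Interactome Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies a seed-gene-associated module in a protein-protein
    interactome by personalized network propagation and screens a drug-target
    library against that module with three independent network statistics:
    closest network proximity, GO-based functional similarity (Wang semantic
    similarity with best-match averaging), and random-walk-with-restart
    diffusion correlation. Each statistic carries a degree-aware permutation
    null (Z-score and empirical P), and drugs significant under all three are
    reported as candidates. Includes module-localization testing (largest
    connected component against degree-matched null), tissue-specificity
    Z-scores from expression matrices, and a synthetic-fixture generator with
    planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
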