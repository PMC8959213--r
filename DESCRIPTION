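Package: qlnrlmf
Title: Drug-Target Interaction Prediction with Q-Learning Weighted
    Similarity Fusion and Neighborhood Regularized Logistic Matrix
    Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts binary drug-target interactions by fusing three
    drug-drug and three target-target similarity matrices with convex
    weights, learning the weights by tabular Q-learning on a discretized
    weight simplex with cross-validated AUC as the reward, and scoring
    interactions with neighborhood regularized logistic matrix
    factorization (logistic matrix factorization with k-nearest-neighbor
    graph-Laplacian regularizers).  Includes readers for the labeled
    tab-separated matrix dialect of the Yamanishi gold-standard
    benchmarks, interaction-profile similarity measures (Tanimoto,
    cosine, Jaccard, normalized Smith-Waterman), a brute-force
    weight-search oracle, pairwise ten-fold cross-validation with AUC and
    AUPR, and a seeded synthetic-data generator with planted low-rank
    structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
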