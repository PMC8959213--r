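# shared fixture builders; everything is generated in code, seeded

random_interactions <- function(m, n, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    y <- matrix(rbinom(m * n, 1, density), m, n,
                dimnames = list(sprintf("d%02d", seq_len(m)),
                                sprintf("t%02d", seq_len(n))))
  })
  if (sum(y) == 0) y[1, 1] <- 1
  if (sum(y) == length(y)) y[1, 1] <- 0
  as_interaction_matrix(y)
}

random_similarity <- function(n, space = "drug", seed = 1, ids = NULL) {
  withr::with_seed(seed, {
    g <- matrix(rnorm(n * 3), n, 3)
  })
  nr <- sqrt(rowSums(g^2))
  s <- (1 + (g %*% t(g)) / (nr %o% nr)) / 2
  diag(s) <- 1
  if (is.null(ids)) {
    ids <- sprintf("%s%02d", if (space == "drug") "d" else "t", seq_len(n))
  }
  dimnames(s) <- list(ids, ids)
  as_similarity_matrix(s, space = space, source = "other")
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# O(n^2) pair-counting AUC used as the independent oracle
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# stepwise average precision by explicit ranking, the independent oracle
aupr_bruteforce <- function(scores, labels) {
  ord <- order(-scores)                       # stable: ascending index on ties
  lab <- labels[ord]
  hits <- 0
  ap <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      hits <- hits + 1
      ap <- ap + hits / i
    }
  }
  ap / sum(labels == 1)
}
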