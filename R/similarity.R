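#' Read per-entity substructure sets
#'
#' One line per entity: `id<TAB>token1,token2,...`; the token list may be
#' empty.  Used as input to [tanimoto_similarity()].
#'
#' @param path Path to the file.
#' @return Named list of character vectors (possibly empty), one per id.
#' @export
read_substructure_sets <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[[2L]])) character(0)
    else unique(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  })
  names(sets) <- ids
  sets
}

#' Tanimoto similarity of substructure sets
#'
#' The Tanimoto coefficient \eqn{|d_i \cap d_j| / |d_i \cup d_j|} between
#' the substructure sets of two compounds.  The diagonal is 1 by
#' definition, including for empty sets; an off-diagonal pair involving an
#' empty set scores 0 (the 0/0 convention).
#'
#' @param sets Named list of character vectors, as from
#'   [read_substructure_sets()].
#' @return A drug-space [as_similarity_matrix()] with source `"tanimoto"`.
#' @examples
#' tanimoto_similarity(list(d1 = c("A", "B", "C"), d2 = c("B", "C", "D")))
#' @export
tanimoto_similarity <- function(sets) {
  ids <- names(sets)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sets must be a named list with unique names")
  }
  n <- length(sets)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        uni <- length(union(sets[[i]], sets[[j]]))
        m[i, j] <- m[j, i] <- if (uni == 0L) 0 else inter / uni
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  as_similarity_matrix(m, space = "drug", source = "tanimoto")
}

#' Interaction-profile cosine similarity
#'
#' Cosine similarity between binary interaction profiles:
#' \eqn{|d_i \cap d_j| / (\sqrt{|d_i|}\sqrt{|d_j|})} over the rows of the
#' (training) interaction matrix for drugs, or over its columns for
#' targets.  Intersection and profile sizes are integer counts, so the
#' result is exact.  If either profile is empty the off-diagonal entry is
#' 0; the diagonal is always 1.
#'
#' @param Y An [as_interaction_matrix()] (drugs in rows).  In
#'   cross-validation this must be the masked training matrix, never the
#'   full matrix, or test labels leak into the similarity.
#' @param space `"drug"` (row profiles) or `"target"` (column profiles).
#' @return A [as_similarity_matrix()] with source `"cosine"`.
#' @export
profile_cosine <- function(Y, space = c("drug", "target")) {
  space <- match.arg(space)
  P <- unclass_matrix(Y)
  if (space == "target") P <- t(P)
  inter <- P %*% t(P)                      # integer pair counts
  sz <- diag(inter)
  denom <- sqrt(sz) %o% sqrt(sz)
  s <- ifelse(denom > 0, inter / denom, 0)
  diag(s) <- 1
  as_similarity_matrix(s, space = space, source = "cosine")
}

#' Interaction-profile Jaccard similarity
#'
#' Jaccard coefficient \eqn{|\cap| / |\cup|} between binary interaction
#' profiles (rows for drugs, columns for targets).  Two empty profiles
#' score 0 off-diagonal; the diagonal is always 1.
#'
#' @inheritParams profile_cosine
#' @return A [as_similarity_matrix()] with source `"jaccard"`.
#' @export
profile_jaccard <- function(Y, space = c("drug", "target")) {
  space <- match.arg(space)
  P <- unclass_matrix(Y)
  if (space == "target") P <- t(P)
  inter <- P %*% t(P)
  sz <- diag(inter)
  uni <- outer(sz, sz, `+`) - inter
  s <- ifelse(uni > 0, inter / uni, 0)
  diag(s) <- 1
  as_similarity_matrix(s, space = space, source = "jaccard")
}

#' Normalize a raw Smith-Waterman score matrix
#'
#' Converts raw local-alignment scores into a similarity in \[0, 1\]:
#' \eqn{SW(i,j) / (\sqrt{SW(i,i)}\sqrt{SW(j,j)})}.  Self-scores must be
#' strictly positive; the diagonal of the result is exactly 1.
#'
#' @param raw Square numeric matrix of raw Smith-Waterman scores with
#'   identical row/column names, symmetric within `1e-8`.
#' @param space Entity space of the matrix, `"target"` by default.
#' @return A [as_similarity_matrix()] with source `"sw"`.
#' @export
normalize_sw <- function(raw, space = c("target", "drug")) {
  space <- match.arg(space)
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("raw score matrix must be square")
  d <- diag(raw)
  if (any(d <= 0)) {
    bad <- rownames(raw)[which(d <= 0)]
    if (is.null(bad)) bad <- which(d <= 0)
    stop("non-positive self-score for: ", paste(bad, collapse = ", "))
  }
  if (max(abs(raw - t(raw))) > 1e-8 * max(abs(raw))) {
    stop("raw score matrix is not symmetric")
  }
  s <- raw / (sqrt(d) %o% sqrt(d))
  diag(s) <- 1
  if (max(s) > 1 + 1e-9) {
    stop(sprintf(
      "normalized score %.6g exceeds 1: raw matrix is inconsistent", max(s)))
  }
  as_similarity_matrix(s, space = space, source = "sw")
}

#' Fuse three similarity matrices with convex weights
#'
#' Entrywise convex combination \eqn{w_1 S_1 + w_2 S_2 + w_3 S_3} of three
#' similarity matrices over the same entities.  This is the linear fusion
#' step whose weights the Q-learning search optimizes; any real simplex
#' weights are accepted, not only the 0.1-grid values of the search.
#'
#' @param sims List of three [as_similarity_matrix()] objects with
#'   identical ids and space.
#' @param weights Numeric vector of three nonnegative weights summing to 1
#'   (within `1e-9`).
#' @return The fused [as_similarity_matrix()] with source `"fused"`.
#' @export
fuse_similarities <- function(sims, weights) {
  if (length(sims) != 3L) stop("sims must be a list of three matrices")
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be three nonnegative reals summing to 1")
  }
  ids <- rownames(sims[[1L]])
  space <- attr(sims[[1L]], "space")
  for (s in sims[-1L]) {
    if (!identical(rownames(s), ids) || !identical(attr(s, "space"), space)) {
      stop("all three similarity matrices must share ids and space")
    }
  }
  fused <- weights[1L] * unclass_matrix(sims[[1L]]) +
           weights[2L] * unclass_matrix(sims[[2L]]) +
           weights[3L] * unclass_matrix(sims[[3L]])
  as_similarity_matrix(fused, space = space, source = "fused")
}
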