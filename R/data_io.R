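#' Read a labeled tab-separated matrix
#'
#' Parses the labeled TSV dialect used by the Yamanishi gold-standard
#' drug-target benchmark files (`admat` adjacency and `simmat` similarity
#' matrices): the first line holds tab-separated column identifiers,
#' optionally preceded by an empty cell, and each following line holds a row
#' identifier followed by numeric cells.
#'
#' The benchmark adjacency files are distributed with targets in rows; pass
#' `orientation = "transpose"` to obtain the package's canonical
#' drugs-by-targets layout.
#'
#' @param path Path to the file.
#' @param orientation Either `"as-is"` (default) or `"transpose"`.
#' @return A numeric matrix with row and column names.
#' @examples
#' tf <- tempfile()
#' writeLines(c("\td1\td2", "t1\t1\t0", "t2\t0\t0"), tf)
#' read_labeled_tsv(tf)
#' read_labeled_tsv(tf, orientation = "transpose")
#' @export
read_labeled_tsv <- function(path, orientation = c("as-is", "transpose")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("file does not exist: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("file has no data rows: ", path)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) >= 1L && !nzchar(header[[1L]])) {
    header <- header[-1L]            # empty leading cell above the row ids
  }
  col_ids <- header
  if (anyDuplicated(col_ids)) {
    stop("duplicate column identifier(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  n <- length(col_ids)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifier(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  widths <- lengths(body)
  bad <- which(widths != n + 1L)
  if (length(bad)) {
    stop(sprintf("ragged row at line %d: expected %d cells, found %d",
                 bad[[1L]] + 1L, n + 1L, widths[[bad[[1L]]]] - 1L))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = n,
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      j <- which(is.na(num))[[1L]]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cells[[j]], row_ids[[i]], col_ids[[j]]))
    }
    vals[i, ] <- num
  }
  if (orientation == "transpose") t(vals) else vals
}

#' Write a labeled tab-separated matrix
#'
#' Inverse of [read_labeled_tsv()]: values are printed at full precision so
#' that a write-read round trip reproduces the matrix exactly.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labeled_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("refusing to write an empty matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have row and column names")
  }
  ids <- c(rownames(m), colnames(m))
  if (any(grepl("[\t\n]", ids))) {
    stop("identifiers must not contain tab or newline characters")
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("", colnames(m)), collapse = "\t"), rows), path)
  invisible(path)
}

#' Validate a binary drug-target interaction matrix
#'
#' Checks that every entry is 0 or 1 and returns the matrix classed as an
#' interaction matrix, oriented drugs-by-targets (rows are drugs).
#'
#' @param m Numeric matrix with row names (drug ids) and column names
#'   (target ids); entries must all be 0 or 1.
#' @return The matrix with class `"interaction_matrix"`.
#' @examples
#' y <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("t1", "t2")))
#' as_interaction_matrix(y)
#' @export
as_interaction_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    k <- min(nrow(bad), 5L)
    cells <- apply(bad[seq_len(k), , drop = FALSE], 1L, function(ij) {
      sprintf("[%s, %s] = %g",
              if (is.null(rownames(m))) ij[1] else rownames(m)[ij[1]],
              if (is.null(colnames(m))) ij[2] else colnames(m)[ij[2]],
              m[ij[1], ij[2]])
    })
    stop("interaction matrix must be binary; offending cells: ",
         paste(cells, collapse = ", "),
         if (nrow(bad) > k) sprintf(" (and %d more)", nrow(bad) - k) else "")
  }
  if (sum(m) == 0) {
    warning("interaction matrix contains no interactions")
  }
  structure(m, class = c("interaction_matrix", class(m)))
}

#' Validate a similarity matrix
#'
#' Checks that the matrix is square with matching row/column identifiers,
#' entries in \[0, 1\] and symmetric.  Tiny numeric blemishes are repaired:
#' asymmetry up to `1e-6` is symmetrized as \eqn{(M + M^T)/2} with a
#' warning (asymmetry within `1e-8` silently), and excursions outside
#' \[0, 1\] by at most `1e-9` are clipped.  Anything larger is an error.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param space `"drug"` or `"target"`.
#' @param source Tag recording how the similarity was produced.
#' @return The matrix with class `"similarity_matrix"` and attributes
#'   `space` and `source`.
#' @export
as_similarity_matrix <- function(m, space = c("drug", "target"),
                                 source = c("other", "structure", "sw",
                                            "cosine", "jaccard", "tanimoto",
                                            "fused")) {
  space <- match.arg(space)
  source <- match.arg(source)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop(sprintf("similarity matrix must be square, got %d x %d",
                 nrow(m), ncol(m)))
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("similarity matrix row and column identifiers must be identical")
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance 1e-6",
                 asym))
  }
  if (asym > 1e-8) {
    warning(sprintf("symmetrizing similarity matrix (asymmetry %.3g)", asym))
  }
  if (asym > 0) m <- (m + t(m)) / 2
  lo <- min(m); hi <- max(m)
  if (lo < -1e-9 || hi > 1 + 1e-9) {
    stop(sprintf("similarity values outside [0, 1]: range [%.6g, %.6g]",
                 lo, hi))
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  structure(m, class = c("similarity_matrix", class(m)),
            space = space, source = source)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("Interaction matrix: %d drugs x %d targets, %d interactions (density %.4f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Similarity matrix (%s space, source '%s'): %d x %d entities\n",
              attr(x, "space"), attr(x, "source"), nrow(x), ncol(x)))
  invisible(x)
}

# strip similarity/interaction classes for plain-matrix arithmetic
unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}
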