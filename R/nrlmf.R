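#' Control parameters for NRLMF
#'
#' Collects the hyperparameters of neighborhood regularized logistic matrix
#' factorization.  Symbol hygiene: `alpha_reg`/`beta_reg` are the
#' graph-Laplacian coefficients of the factorization objective; they are
#' unrelated to the Q-learning learning rate or to the fusion weights,
#' which carry those Greek letters elsewhere in the literature.
#'
#' @param r Latent dimension; `NA` means `min(50, min(dim(Y)))` at fit time.
#' @param c Importance weight for observed interactions (>= 1): each
#'   positive cell counts as `c` observations in the logistic likelihood.
#' @param lambda_d,lambda_t Ridge coefficients (> 0) on the drug and target
#'   latent factors.
#' @param alpha_reg,beta_reg Coefficients (>= 0) of the drug and target
#'   graph-Laplacian regularizers.
#' @param K Neighborhood size for the k-nearest-neighbor graph (>= 1).
#' @param learning_rate AdaGrad base step size (> 0).
#' @param max_iter Maximum number of full-gradient iterations (>= 1).
#' @param tol Relative objective-change convergence threshold (>= 0).
#' @param optimizer `"adagrad"` (default) or plain `"gd"`.
#' @param engine `"cpp"` runs the compiled training loop, `"R"` the pure-R
#'   reference loop; both implement the identical update and are checked
#'   against each other in the test suite.
#' @return A list of class `"nrlmf_control"`.
#' @export
nrlmf_control <- function(r = NA, c = 5, lambda_d = 0.625, lambda_t = 0.625,
                          alpha_reg = 1, beta_reg = 1, K = 5,
                          learning_rate = 0.5, max_iter = 100, tol = 1e-5,
                          optimizer = c("adagrad", "gd"),
                          engine = c("cpp", "R")) {
  optimizer <- match.arg(optimizer)
  engine <- match.arg(engine)
  stopifnot(is.na(r) || (r >= 1 && r == round(r)),
            c >= 1, lambda_d > 0, lambda_t > 0,
            alpha_reg >= 0, beta_reg >= 0,
            K >= 1, K == round(K),
            learning_rate > 0, max_iter >= 1, tol >= 0)
  structure(list(r = r, c = c, lambda_d = lambda_d, lambda_t = lambda_t,
                 alpha_reg = alpha_reg, beta_reg = beta_reg, K = K,
                 learning_rate = learning_rate, max_iter = max_iter,
                 tol = tol, optimizer = optimizer, engine = engine),
            class = "nrlmf_control")
}

#' k-nearest-neighbor graph Laplacian
#'
#' Sparsifies a similarity matrix to each entity's `K` most similar
#' neighbors (self excluded; ties broken by ascending index) and returns
#' the graph Laplacian of the symmetrized neighbor graph:
#' \eqn{L = D_{row} + D_{col} - (A + A^T)}, where `A` keeps `S[i, j]` iff
#' `j` is among the `K` nearest neighbors of `i` and `D_row`, `D_col` are
#' the diagonal row/column sum matrices of `A`.  `L` is symmetric,
#' positive semidefinite, with zero row sums.
#'
#' @param S Square symmetric similarity matrix.
#' @param K Neighbors per entity; must be less than `nrow(S)`.
#' @return The Laplacian matrix.
#' @export
build_knn_laplacian <- function(S, K) {
  S <- unclass_matrix(as.matrix(S))
  n <- nrow(S)
  if (K >= n) stop(sprintf("K = %d must be smaller than the number of entities (%d)", K, n))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sims <- S[i, ]
    sims[i] <- -Inf
    # ties broken by ascending index: order() is stable on ties
    nb <- order(sims, decreasing = TRUE)[seq_len(K)]
    A[i, nb] <- S[i, nb]
  }
  L <- diag(rowSums(A)) + diag(colSums(A)) - (A + t(A))
  dimnames(L) <- dimnames(S)
  L
}

# softplus log(1 + exp(z)) without overflow for large |z|
softplus <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

#' NRLMF objective function
#'
#' The regularized weighted logistic loss
#' \deqn{\sum_{ij} (1 + c y_{ij} - y_{ij}) \ln(1 + e^{u_i v_j^T})
#'       - c y_{ij} u_i v_j^T
#'       + \tfrac12 tr[U^T(\lambda_d I + \alpha L_d)U]
#'       + \tfrac12 tr[V^T(\lambda_t I + \beta L_t)V]}
#' computed with an overflow-safe softplus.
#'
#' @param U,V Latent factor matrices (m x r and n x r).
#' @param Y Binary interaction matrix (m x n).
#' @param L_d,L_t Drug and target graph Laplacians.
#' @param control An [nrlmf_control()] list.
#' @return The scalar objective value.
#' @export
nrlmf_objective <- function(U, V, Y, L_d, L_t, control) {
  Y <- unclass_matrix(as.matrix(Y))
  stopifnot(nrow(U) == nrow(Y), nrow(V) == ncol(Y), ncol(U) == ncol(V),
            all(dim(L_d) == nrow(Y)), all(dim(L_t) == ncol(Y)))
  Z <- U %*% t(V)
  W <- 1 + control$c * Y - Y
  loss <- sum(W * softplus(Z)) - control$c * sum(Y * Z)
  reg_u <- 0.5 * (control$lambda_d * sum(U * U) +
                  control$alpha_reg * sum(U * (L_d %*% U)))
  reg_v <- 0.5 * (control$lambda_t * sum(V * V) +
                  control$beta_reg * sum(V * (L_t %*% V)))
  loss + reg_u + reg_v
}

#' NRLMF analytic gradients
#'
#' Partial gradients of [nrlmf_objective()] with respect to `U` and `V`:
#' \deqn{\partial L/\partial U = PV + (c-1)(Y \odot P)V - cYV
#'       + (\lambda_d I + \alpha L_d)U}
#' and the mirrored expression for `V`, where
#' \eqn{P = \sigma(UV^T)} and \eqn{\odot} is the Hadamard product.
#'
#' @inheritParams nrlmf_objective
#' @return List with components `dU` (m x r) and `dV` (n x r).
#' @export
nrlmf_gradients <- function(U, V, Y, L_d, L_t, control) {
  Y <- unclass_matrix(as.matrix(Y))
  Z <- U %*% t(V)
  P <- 1 / (1 + exp(-Z))
  c_ <- control$c
  G <- P + (c_ - 1) * (Y * P) - c_ * Y     # shared m x n factor
  dU <- G %*% V + control$lambda_d * U + control$alpha_reg * (L_d %*% U)
  dV <- t(G) %*% U + control$lambda_t * V + control$beta_reg * (L_t %*% V)
  list(dU = dU, dV = dV)
}

#' Fit a neighborhood regularized logistic matrix factorization model
#'
#' Models the probability of a drug-target interaction as
#' \eqn{P_{ij} = \sigma(u_i v_j^T)} with latent vectors regularized
#' towards their k-nearest similarity neighbors through graph Laplacians
#' built from the drug and target similarity matrices.  Training minimizes
#' [nrlmf_objective()] by full-gradient AdaGrad (per-element accumulated
#' squared gradients) from a seeded Gaussian initialization scaled by
#' \eqn{1/\sqrt{r}}; the run is deterministic given `seed`.
#'
#' @param Y An [as_interaction_matrix()] (drugs in rows).  In
#'   cross-validation pass the masked training matrix.
#' @param S_drug,S_target Similarity matrices whose ids match the rows and
#'   columns of `Y` respectively.
#' @param control An [nrlmf_control()] list of hyperparameters.
#' @param seed Integer seed for the factor initialization.
#' @param L_d,L_t Optional precomputed graph Laplacians (as from
#'   [build_knn_laplacian()]); built from the similarity matrices when
#'   `NULL`.  Useful when many models share the same neighborhood graph.
#' @return An object of class `"nrlmf"` with components `U`, `V`, `L_d`,
#'   `L_t`, `control`, `objective_trace`, `converged`, `Y_train`.
#' @examples
#' set.seed(1)
#' y <- matrix(rbinom(60, 1, 0.3), 10, 6,
#'             dimnames = list(paste0("d", 1:10), paste0("t", 1:6)))
#' Y <- as_interaction_matrix(y)
#' Sd <- profile_cosine(Y, "drug"); St <- profile_cosine(Y, "target")
#' fit <- nrlmf(Y, Sd, St, nrlmf_control(r = 3, max_iter = 30), seed = 7)
#' fit
#' @export
nrlmf <- function(Y, S_drug, S_target, control = nrlmf_control(), seed = 1L,
                  L_d = NULL, L_t = NULL) {
  m <- nrow(Y); n <- ncol(Y)
  if (!is.null(rownames(Y)) && !is.null(rownames(S_drug)) &&
      !identical(rownames(Y), rownames(S_drug))) {
    stop("drug ids of Y and S_drug do not match")
  }
  if (!is.null(colnames(Y)) && !is.null(rownames(S_target)) &&
      !identical(colnames(Y), rownames(S_target))) {
    stop("target ids of Y and S_target do not match")
  }
  r <- if (is.na(control$r)) min(50L, m, n) else as.integer(control$r)
  if (is.null(L_d)) L_d <- build_knn_laplacian(S_drug, min(control$K, m - 1L))
  if (is.null(L_t)) L_t <- build_knn_laplacian(S_target, min(control$K, n - 1L))
  Ym <- unclass_matrix(as.matrix(Y))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  U <- matrix(stats::rnorm(m * r), m, r) / sqrt(r)
  V <- matrix(stats::rnorm(n * r), n, r) / sqrt(r)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  if (identical(control$engine, "cpp")) {
    res <- .nrlmf_fit_cpp(Ym, L_d, L_t, U, V,
                          control$c, control$lambda_d, control$lambda_t,
                          control$alpha_reg, control$beta_reg,
                          control$learning_rate, control$max_iter,
                          control$tol, control$optimizer == "adagrad")
    U <- res$U; V <- res$V
    trace <- res$objective_trace
    converged <- res$converged
  } else {
    lr <- control$learning_rate
    c_ <- control$c
    gU <- matrix(0, m, r); gV <- matrix(0, n, r)
    eps <- 1e-8
    trace <- numeric(control$max_iter)
    W <- 1 + c_ * Ym - Ym
    LdA <- control$lambda_d * diag(m) + control$alpha_reg * L_d
    LtA <- control$lambda_t * diag(n) + control$beta_reg * L_t
    obj_prev <- Inf
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(control$max_iter)) {
      # objective and gradient share the logit matrix of the current point
      Z <- U %*% t(V)
      RU <- LdA %*% U
      RV <- LtA %*% V
      obj <- sum(W * softplus(Z)) - c_ * sum(Ym * Z) +
        0.5 * (sum(U * RU) + sum(V * RV))
      if (!is.finite(obj)) {
        stop("objective became non-finite during training; ",
             "try a smaller learning_rate")
      }
      trace[it] <- obj
      iters <- it
      if (abs(obj - obj_prev) / max(abs(obj), .Machine$double.eps) < control$tol) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
      P <- 1 / (1 + exp(-Z))
      G <- P + (c_ - 1) * (Ym * P) - c_ * Ym
      dU <- G %*% V + RU
      dV <- crossprod(G, U) + RV
      if (control$optimizer == "adagrad") {
        gU <- gU + dU^2
        gV <- gV + dV^2
        U <- U - lr * dU / sqrt(gU + eps)
        V <- V - lr * dV / sqrt(gV + eps)
      } else {
        U <- U - lr * dU
        V <- V - lr * dV
      }
    }
    trace <- trace[seq_len(iters)]
  }
  dimnames(U) <- NULL
  dimnames(V) <- NULL
  structure(list(U = U, V = V, L_d = L_d, L_t = L_t,
                 control = control, r = r, seed = seed,
                 objective_trace = trace,
                 converged = converged,
                 Y_train = Ym,
                 S_drug = unclass_matrix(as.matrix(S_drug)),
                 S_target = unclass_matrix(as.matrix(S_target)),
                 call = match.call()),
            class = "nrlmf")
}

# neighbor-smoothed latent vectors for entities with empty training profiles:
# the latent vector of a cold entity is replaced by the similarity-weighted
# mean of its K nearest neighbors' vectors (weights = similarities, renormalized)
smooth_cold <- function(F_, S, cold, K) {
  n <- nrow(S)
  for (i in cold) {
    sims <- S[i, ]
    sims[i] <- -Inf
    nb <- order(sims, decreasing = TRUE)[seq_len(min(K, n - 1L))]
    w <- S[i, nb]
    if (sum(w) > 0) {
      F_[i, ] <- colSums(F_[nb, , drop = FALSE] * (w / sum(w)))
    }
  }
  F_
}

#' Predict interaction probabilities from a fitted NRLMF model
#'
#' Returns \eqn{P = \sigma(UV^T)}.  Cold-start entities -- drugs or
#' targets whose training row/column is all zero -- first have their
#' latent vector replaced by the similarity-weighted mean of their `K`
#' nearest neighbors' vectors, so their scores reflect the similarity
#' graph rather than an arbitrary initialization.
#'
#' @param object A fitted `"nrlmf"` model.
#' @param ... Unused.
#' @return An m x n matrix of probabilities in (0, 1).
#' @export
predict.nrlmf <- function(object, ...) {
  U <- object$U; V <- object$V
  cold_d <- which(rowSums(object$Y_train) == 0)
  cold_t <- which(colSums(object$Y_train) == 0)
  if (length(cold_d)) U <- smooth_cold(U, object$S_drug, cold_d, object$control$K)
  if (length(cold_t)) V <- smooth_cold(V, object$S_target, cold_t, object$control$K)
  P <- 1 / (1 + exp(-U %*% t(V)))
  dimnames(P) <- dimnames(object$Y_train)
  P
}

#' @export
print.nrlmf <- function(x, ...) {
  cat("Neighborhood regularized logistic matrix factorization\n")
  cat(sprintf("  %d drugs x %d targets, latent dimension r = %d\n",
              nrow(x$U), nrow(x$V), x$r))
  cat(sprintf("  c = %g, lambda = (%g, %g), laplacian = (%g, %g), K = %d\n",
              x$control$c, x$control$lambda_d, x$control$lambda_t,
              x$control$alpha_reg, x$control$beta_reg, x$control$K))
  cat(sprintf("  %d iterations (%s), final objective %.4f\n",
              length(x$objective_trace),
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' @export
summary.nrlmf <- function(object, ...) {
  P <- predict(object)
  obs <- object$Y_train == 1
  out <- list(model = object,
              mean_p_positive = mean(P[obs]),
              mean_p_negative = mean(P[!obs]),
              train_auc = if (any(obs) && !all(obs))
                auc_score(as.vector(P), as.vector(object$Y_train))
                else NA_real_)
  class(out) <- "summary.nrlmf"
  out
}

#' @export
print.summary.nrlmf <- function(x, ...) {
  print(x$model)
  cat(sprintf("  mean fitted P: positives %.3f, negatives %.3f\n",
              x$mean_p_positive, x$mean_p_negative))
  if (!is.na(x$train_auc)) cat(sprintf("  training AUC %.4f\n", x$train_auc))
  invisible(x)
}

#' @export
coef.nrlmf <- function(object, ...) {
  list(U = object$U, V = object$V)
}

#' @export
fitted.nrlmf <- function(object, ...) {
  predict(object)
}

#' @export
residuals.nrlmf <- function(object, ...) {
  object$Y_train - predict(object)
}

#' Plot the NRLMF objective trace
#'
#' @param x A fitted `"nrlmf"` model.
#' @param ... Passed to [plot()].
#' @export
plot.nrlmf <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace, type = "l",
                 xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}

#' Export a fitted NRLMF model to a directory of text files
#'
#' Writes `U.tsv`, `V.tsv`, `objective_trace.tsv` in the labeled-TSV
#' dialect plus `metadata.txt` with key-value hyperparameters.
#'
#' @param model A fitted `"nrlmf"` model.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
export_nrlmf <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  U <- model$U; V <- model$V
  dimnames(U) <- list(rownames(model$Y_train) %||% paste0("d", seq_len(nrow(U))),
                      paste0("f", seq_len(ncol(U))))
  dimnames(V) <- list(colnames(model$Y_train) %||% paste0("t", seq_len(nrow(V))),
                      paste0("f", seq_len(ncol(V))))
  write_labeled_tsv(U, file.path(dir, "U.tsv"))
  write_labeled_tsv(V, file.path(dir, "V.tsv"))
  tr <- matrix(model$objective_trace, ncol = 1,
               dimnames = list(seq_along(model$objective_trace), "objective"))
  write_labeled_tsv(tr, file.path(dir, "objective_trace.tsv"))
  ctl <- model$control
  meta <- c(sprintf("r\t%d", model$r), sprintf("seed\t%d", model$seed),
            vapply(setdiff(names(ctl), "r"), function(k)
              sprintf("%s\t%s", k, format(ctl[[k]])), character(1)))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
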