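test_that("kNN Laplacian matches the hand-computed 2x2 case", {
  ids <- c("a", "b")
  s <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(ids, ids))
  L <- build_knn_laplacian(s, 1)
  expect_equal(unname(L), matrix(c(1, -1, -1, 1), 2, 2))

  # no off-diagonal similarity: the neighbor graph has zero weights
  expect_equal(unname(build_knn_laplacian(diag(3), 1)), matrix(0, 3, 3))

  expect_error(build_knn_laplacian(s, 2), "smaller")
})

test_that("kNN Laplacians are symmetric, zero-row-sum, and PSD", {
  for (seed in 1:4) {
    s <- random_similarity(9, "drug", seed = seed)
    for (K in c(1, 3, 5)) {
      L <- build_knn_laplacian(s, K)
      expect_equal(L, t(L))
      expect_equal(unname(rowSums(L)), rep(0, 9), tolerance = 1e-8)
      expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("Laplacian quadratic form equals the pairwise-distance double loop", {
  s <- random_similarity(7, "drug", seed = 5)
  K <- 3
  L <- build_knn_laplacian(s, K)
  withr::with_seed(8, U <- matrix(rnorm(7 * 2), 7, 2))
  # reconstruct A as build_knn_laplacian defines it
  A <- matrix(0, 7, 7)
  for (i in 1:7) {
    sims <- unclass(s)[i, ]; sims[i] <- -Inf
    nb <- order(sims, decreasing = TRUE)[1:K]
    A[i, nb] <- unclass(s)[i, nb]
  }
  W <- A + t(A)
  quad <- 0
  for (i in 1:7) for (j in 1:7) {
    quad <- quad + W[i, j] * sum((U[i, ] - U[j, ])^2) / 2
  }
  expect_equal(sum(U * (L %*% U)), quad, tolerance = 1e-10)
})

test_that("objective matches closed forms at the zero point", {
  ctl <- nrlmf_control(c = 5, alpha_reg = 0, beta_reg = 0,
                       lambda_d = 1, lambda_t = 1)
  U <- matrix(0, 2, 2); V <- matrix(0, 2, 2)
  L0 <- matrix(0, 2, 2)
  y1 <- matrix(c(1, 0, 0, 0), 2, 2)
  # one positive: (3 * 1 + 1 * 5) * ln 2, regularizers vanish at zero
  expect_equal(nrlmf_objective(U, V, y1, L0, L0, ctl), 8 * log(2))
  # all-zero labels: m * n * ln 2
  expect_equal(nrlmf_objective(U, V, matrix(0, 2, 2), L0, L0, ctl),
               4 * log(2))
})

test_that("objective matches a naive scalar double loop", {
  withr::with_seed(11, {
    m <- 5; n <- 4; r <- 2
    Y <- matrix(rbinom(m * n, 1, 0.3), m, n)
    U <- matrix(rnorm(m * r), m, r)
    V <- matrix(rnorm(n * r), n, r)
    Sd <- random_similarity(m, "drug", seed = 21)
    St <- random_similarity(n, "target", seed = 22)
  })
  Ld <- build_knn_laplacian(Sd, 2)
  Lt <- build_knn_laplacian(St, 2)
  ctl <- nrlmf_control(c = 5, lambda_d = 0.625, lambda_t = 0.5,
                       alpha_reg = 0.3, beta_reg = 0.7)
  naive <- 0
  for (i in 1:m) for (j in 1:n) {
    z <- sum(U[i, ] * V[j, ])
    naive <- naive + (1 + ctl$c * Y[i, j] - Y[i, j]) * log(1 + exp(z)) -
      ctl$c * Y[i, j] * z
  }
  naive <- naive +
    0.5 * sum(diag(t(U) %*% (ctl$lambda_d * diag(m) + ctl$alpha_reg * Ld) %*% U)) +
    0.5 * sum(diag(t(V) %*% (ctl$lambda_t * diag(n) + ctl$beta_reg * Lt) %*% V))
  expect_equal(nrlmf_objective(U, V, Y, Ld, Lt, ctl), naive,
               tolerance = 1e-10)
})

test_that("softplus-based objective survives extreme logits", {
  ctl <- nrlmf_control(alpha_reg = 0, beta_reg = 0)
  U <- matrix(1000, 1, 1); V <- matrix(1000, 1, 1)
  L0 <- matrix(0, 1, 1)
  val <- nrlmf_objective(U, V, matrix(0, 1, 1), L0, L0, ctl)
  expect_true(is.finite(val))
  expect_equal(val, 1e6 + 0.5 * ctl$lambda_d * 1e6 + 0.5 * ctl$lambda_t * 1e6,
               tolerance = 1e-6)
})

test_that("analytic gradients agree with central finite differences", {
  fd_grad <- function(U, V, Y, Ld, Lt, ctl, h = 1e-6) {
    dU <- U * 0
    for (i in seq_len(nrow(U))) for (k in seq_len(ncol(U))) {
      up <- U; up[i, k] <- up[i, k] + h
      dn <- U; dn[i, k] <- dn[i, k] - h
      dU[i, k] <- (nrlmf_objective(up, V, Y, Ld, Lt, ctl) -
                   nrlmf_objective(dn, V, Y, Ld, Lt, ctl)) / (2 * h)
    }
    dV <- V * 0
    for (j in seq_len(nrow(V))) for (k in seq_len(ncol(V))) {
      up <- V; up[j, k] <- up[j, k] + h
      dn <- V; dn[j, k] <- dn[j, k] - h
      dV[j, k] <- (nrlmf_objective(U, up, Y, Ld, Lt, ctl) -
                   nrlmf_objective(U, dn, Y, Ld, Lt, ctl)) / (2 * h)
    }
    list(dU = dU, dV = dV)
  }
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- sample(4:8, 1); n <- sample(4:8, 1); r <- sample(2:3, 1)
      Y <- matrix(rbinom(m * n, 1, 0.4), m, n)
      U <- matrix(rnorm(m * r), m, r)
      V <- matrix(rnorm(n * r), n, r)
    })
    Ld <- build_knn_laplacian(random_similarity(m, "drug", seed = seed + 40), 2)
    Lt <- build_knn_laplacian(random_similarity(n, "target", seed = seed + 80), 2)
    ctl <- nrlmf_control(c = 4, alpha_reg = 0.3, beta_reg = 0.2)
    g <- nrlmf_gradients(U, V, Y, Ld, Lt, ctl)
    fd <- fd_grad(U, V, Y, Ld, Lt, ctl)
    expect_equal(g$dU, fd$dU, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(g$dV, fd$dV, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("gradients vanish at the origin and reduce to logistic loss", {
  ctl0 <- nrlmf_control(lambda_d = 1e-12, lambda_t = 1e-12,
                        alpha_reg = 0, beta_reg = 0, c = 1)
  L2 <- matrix(0, 2, 2)
  g0 <- nrlmf_gradients(matrix(0, 2, 2), matrix(0, 2, 2),
                        matrix(c(1, 0, 0, 0), 2, 2), L2, L2, ctl0)
  expect_equal(g0$dU, matrix(0, 2, 2))
  expect_equal(g0$dV, matrix(0, 2, 2))

  # single observed cell, c = 1: the classic (P - y) * v logistic gradient
  withr::with_seed(3, { u <- matrix(rnorm(2), 1, 2); v <- matrix(rnorm(2), 1, 2) })
  y <- matrix(1, 1, 1)
  L1 <- matrix(0, 1, 1)
  g <- nrlmf_gradients(u, v, y, L1, L1, ctl0)
  p <- 1 / (1 + exp(-sum(u * v)))
  expect_equal(g$dU, (p - 1) * v, tolerance = 1e-9)
})

test_that("fitting is deterministic and the objective decreases", {
  Y <- random_interactions(20, 15, density = 0.15, seed = 7)
  Sd <- random_similarity(20, "drug", seed = 7)
  St <- random_similarity(15, "target", seed = 8)
  ctl <- nrlmf_control(r = 5, max_iter = 40)
  f1 <- nrlmf(Y, Sd, St, ctl, seed = 99)
  f2 <- nrlmf(Y, Sd, St, ctl, seed = 99)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  tr <- f1$objective_trace
  expect_true(all(is.finite(tr)))
  expect_lt(tr[length(tr)], tr[1])
})

test_that("the compiled and reference training loops agree", {
  Y <- random_interactions(12, 9, density = 0.2, seed = 3)
  Sd <- random_similarity(12, "drug", seed = 4)
  St <- random_similarity(9, "target", seed = 5)
  fc <- nrlmf(Y, Sd, St, nrlmf_control(r = 4, max_iter = 30), seed = 2)
  fr <- nrlmf(Y, Sd, St, nrlmf_control(r = 4, max_iter = 30, engine = "R"),
              seed = 2)
  expect_equal(fc$U, fr$U, tolerance = 1e-10)
  expect_equal(fc$V, fr$V, tolerance = 1e-10)
  expect_equal(fc$objective_trace, fr$objective_trace, tolerance = 1e-10)
})

test_that("plain logistic MF separates a separable toy problem", {
  y <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("d1", "d2"), c("t1", "t2")))
  Y <- suppressWarnings(as_interaction_matrix(y))
  sd_ <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("d1", "d2"), c("d1", "d2")))
  st_ <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  Sd <- as_similarity_matrix(sd_, "drug")
  St <- as_similarity_matrix(st_, "target")
  ctl <- nrlmf_control(r = 2, alpha_reg = 0, beta_reg = 0,
                       lambda_d = 0.01, lambda_t = 0.01,
                       max_iter = 300, K = 1)
  fit <- nrlmf(Y, Sd, St, ctl, seed = 1)
  P <- 1 / (1 + exp(-fit$U %*% t(fit$V)))
  expect_gt(P[1, 1], max(P[1, 2], P[2, 1], P[2, 2]))
})

test_that("predictions are probabilities and cold starts borrow from neighbors", {
  y <- rbind(d1 = c(1, 0, 1), d2 = c(0, 1, 0), d3 = c(0, 0, 0))
  colnames(y) <- paste0("t", 1:3)
  Y <- as_interaction_matrix(y)
  ids <- rownames(y)
  # d3 has no training interactions; its only similar drug is d1
  sd_ <- matrix(c(1, 0, 1,
                  0, 1, 0,
                  1, 0, 1), 3, 3, byrow = TRUE, dimnames = list(ids, ids))
  Sd <- as_similarity_matrix(sd_, "drug")
  St <- random_similarity(3, "target", seed = 9, ids = paste0("t", 1:3))
  fit <- nrlmf(Y, Sd, St, nrlmf_control(r = 2, K = 1, max_iter = 30), seed = 4)
  P <- predict(fit)
  expect_true(all(P > 0 & P < 1))
  # the cold drug inherits its unit-similarity neighbor's latent vector
  Pman <- 1 / (1 + exp(-rbind(fit$U[1, ], fit$U[2, ], fit$U[1, ]) %*% t(fit$V)))
  expect_equal(unname(P[3, ]), unname(Pman[3, ]), tolerance = 1e-12)
  expect_equal(unname(P[3, ]), unname(P[1, ]), tolerance = 1e-12)
})

test_that("model accessors and export work", {
  Y <- random_interactions(8, 6, seed = 12)
  Sd <- random_similarity(8, "drug", seed = 12)
  St <- random_similarity(6, "target", seed = 13)
  fit <- nrlmf(Y, Sd, St, nrlmf_control(r = 3, max_iter = 20), seed = 5)
  expect_named(coef(fit), c("U", "V"))
  expect_equal(dim(fitted(fit)), dim(Y))
  expect_equal(residuals(fit), unclass(Y) - fitted(fit), ignore_attr = TRUE)
  expect_output(print(fit), "logistic matrix factorization")
  expect_output(print(summary(fit)), "mean fitted P")

  dir <- withr::local_tempdir()
  export_nrlmf(fit, dir)
  U2 <- read_labeled_tsv(file.path(dir, "U.tsv"))
  expect_equal(unname(U2), unname(fit$U), tolerance = 0)
  expect_true(file.exists(file.path(dir, "metadata.txt")))
})

test_that("id misalignment between Y and similarities is an error", {
  Y <- random_interactions(5, 4, seed = 1)
  Sd <- random_similarity(5, "drug", seed = 1,
                          ids = sprintf("x%02d", 1:5))
  St <- random_similarity(4, "target", seed = 2)
  expect_error(nrlmf(Y, Sd, St), "do not match")
})
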