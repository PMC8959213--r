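#' Simulate a drug-target interaction problem with planted structure
#'
#' Generates a seeded synthetic dataset on which the whole pipeline is
#' testable without downloads.  Latent factors \eqn{U^*} (m x r) and
#' \eqn{V^*} (n x r) are drawn standard normal; interaction probabilities
#' are \eqn{P^* = \sigma(s \cdot U^*V^{*T} + b)} with the scale `s`
#' fixing the latent logit spread and the offset `b` solved numerically so
#' that the mean of \eqn{P^*} matches `density`; `Y` is sampled
#' element-wise Bernoulli.  The ground-truth similarity in each space is
#' the cosine similarity of the latent rows mapped to \[0, 1\] via
#' \eqn{(1 + \cos)/2}; each released matrix blends it with a decoy,
#' \eqn{(1-\nu)\,truth + \nu\,decoy}, so the three matrices per space
#' carry controlled, unequal information about the interactions.  The
#' decoy is itself a latent-cosine similarity built from independent
#' random factors: an internally consistent similarity view whose
#' neighborhoods are simply unrelated to the interactions, which is how an
#' uninformative data source looks in practice.  The smallest noise level
#' marks the informative matrix the weight search should up-weight.
#'
#' @param m,n Numbers of drugs and targets (>= 5).
#' @param r_true Planted latent rank (<= min(m, n)).
#' @param density Target fraction of positive pairs, in (0, 0.5].
#' @param noise_drug,noise_target Three noise levels in \[0, 1\] per
#'   space; level 0 releases the truth unchanged.
#' @param logit_sd Spread of the latent logits before the offset; larger
#'   values make interactions more predictable.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A list of class `"dti_simulation"`: `Y`
#'   ([as_interaction_matrix()]), `drug_sims` and `target_sims` (lists of
#'   three similarity matrices), and `truth` (list with `U`, `V`,
#'   `informative_drug`, `informative_target`, the noise levels and
#'   `P_star`).
#' @examples
#' sim <- simulate_dti(m = 20, n = 15, r_true = 3, seed = 1)
#' sim$Y
#' @export
simulate_dti <- function(m = 40L, n = 30L, r_true = 4L, density = 0.1,
                         noise_drug = c(0.05, 0.6, 0.6),
                         noise_target = c(0.05, 0.6, 0.6),
                         logit_sd = 4, seed = 1L) {
  if (m < 5L || n < 5L) stop("m and n must be at least 5")
  if (r_true > min(m, n)) stop("r_true must not exceed min(m, n)")
  if (density <= 0 || density > 0.5) stop("density must lie in (0, 0.5]")
  if (length(noise_drug) != 3L || length(noise_target) != 3L ||
      any(c(noise_drug, noise_target) < 0) ||
      any(c(noise_drug, noise_target) > 1)) {
    stop("noise levels must be three values in [0, 1] per space")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  U <- matrix(stats::rnorm(m * r_true), m, r_true)
  V <- matrix(stats::rnorm(n * r_true), n, r_true)
  Z <- U %*% t(V)
  Z <- Z * (logit_sd / stats::sd(Z))        # fix the logit spread
  # offset solved so mean predicted probability hits the target density
  f <- function(b) mean(stats::plogis(Z + b)) - density
  b <- tryCatch(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root,
                error = function(e)
                  stop("could not solve the density offset; ",
                       "adjust density or logit_sd"))
  P_star <- stats::plogis(Z + b)
  drug_ids <- sprintf("d%02d", seq_len(m))
  target_ids <- sprintf("t%02d", seq_len(n))
  Y <- matrix(stats::rbinom(m * n, 1L, P_star), m, n,
              dimnames = list(drug_ids, target_ids))
  # a fully empty matrix breaks downstream AUC; resample the rare all-zero
  # draw deterministically
  while (sum(Y) == 0) {
    Y <- matrix(stats::rbinom(m * n, 1L, P_star), m, n,
                dimnames = list(drug_ids, target_ids))
  }

  latent_truth <- function(F_, ids) {
    nrm <- sqrt(rowSums(F_^2))
    cosine <- (F_ %*% t(F_)) / (nrm %o% nrm)
    s <- (1 + cosine) / 2
    diag(s) <- 1
    dimnames(s) <- list(ids, ids)
    s
  }
  noisy_copies <- function(truth, nus, space) {
    nn <- nrow(truth)
    lapply(nus, function(nu) {
      decoy <- latent_truth(matrix(stats::rnorm(nn * r_true), nn, r_true),
                            rownames(truth))
      blended <- (1 - nu) * truth + nu * decoy
      diag(blended) <- 1
      dimnames(blended) <- dimnames(truth)
      as_similarity_matrix(blended, space = space, source = "other")
    })
  }
  truth_d <- latent_truth(U, drug_ids)
  truth_t <- latent_truth(V, target_ids)
  drug_sims <- noisy_copies(truth_d, noise_drug, "drug")
  target_sims <- noisy_copies(truth_t, noise_target, "target")

  structure(list(
    Y = suppressWarnings(as_interaction_matrix(Y)),
    drug_sims = drug_sims,
    target_sims = target_sims,
    truth = list(U = U, V = V, P_star = P_star,
                 noise_drug = noise_drug, noise_target = noise_target,
                 informative_drug = which.min(noise_drug),
                 informative_target = which.min(noise_target)),
    settings = list(m = m, n = n, r_true = r_true, density = density,
                logit_sd = logit_sd, seed = seed)),
    class = "dti_simulation")
}

#' @export
print.dti_simulation <- function(x, ...) {
  cat(sprintf("Synthetic DTI dataset: %d drugs x %d targets, rank %d, %d interactions (density %.3f)\n",
              x$settings$m, x$settings$n, x$settings$r_true, sum(x$Y), mean(x$Y)))
  cat(sprintf("  drug noise levels   (%s), informative matrix %d\n",
              paste(x$truth$noise_drug, collapse = ", "),
              x$truth$informative_drug))
  cat(sprintf("  target noise levels (%s), informative matrix %d\n",
              paste(x$truth$noise_target, collapse = ", "),
              x$truth$informative_target))
  invisible(x)
}

#' Did the weight search recover the planted informative matrices?
#'
#' `TRUE` iff the best state assigns its maximal drug weight to the most
#' informative (least noisy) drug similarity matrix and likewise for the
#' target space.
#'
#' @param best_state Six-tenths integer state vector (or a `"qlearn"`
#'   object, whose `best_state` is used).
#' @param truth The `truth` component of a [simulate_dti()] dataset.
#' @return Logical flag.
#' @export
planted_weight_check <- function(best_state, truth) {
  if (inherits(best_state, "qlearn")) best_state <- best_state$best_state
  s <- as.integer(best_state)
  which.max(s[1:3]) == truth$informative_drug &&
    which.max(s[4:6]) == truth$informative_target
}

#' Write a synthetic dataset to disk as labeled TSV files
#'
#' Produces `Y.tsv` plus `drug_sim_{1,2,3}.tsv` and
#' `target_sim_{1,2,3}.tsv` in the labeled-TSV dialect, and a
#' `truth.txt` key-value metadata file recording the generator settings
#' and the planted informative indices.
#'
#' @param sim A [simulate_dti()] dataset.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labeled_tsv(unclass_matrix(sim$Y), file.path(dir, "Y.tsv"))
  for (i in 1:3) {
    write_labeled_tsv(unclass_matrix(sim$drug_sims[[i]]),
                      file.path(dir, sprintf("drug_sim_%d.tsv", i)))
    write_labeled_tsv(unclass_matrix(sim$target_sims[[i]]),
                      file.path(dir, sprintf("target_sim_%d.tsv", i)))
  }
  meta <- c(sprintf("m\t%d", sim$settings$m),
            sprintf("n\t%d", sim$settings$n),
            sprintf("r_true\t%d", sim$settings$r_true),
            sprintf("density\t%g", sim$settings$density),
            sprintf("logit_sd\t%g", sim$settings$logit_sd),
            sprintf("seed\t%d", sim$settings$seed),
            sprintf("noise_drug\t%s", paste(sim$truth$noise_drug, collapse = ",")),
            sprintf("noise_target\t%s", paste(sim$truth$noise_target, collapse = ",")),
            sprintf("informative_drug\t%d", sim$truth$informative_drug),
            sprintf("informative_target\t%d", sim$truth$informative_target))
  writeLines(meta, file.path(dir, "truth.txt"))
  invisible(dir)
}
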