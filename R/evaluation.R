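#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of positive-negative pairs in which the
#' positive scores higher, tied pairs counting one half.  Computed from
#' midranks, which is exactly the pair-counting definition.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length as `scores`; both
#'   classes must be present.
#' @return The AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC requires at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: predictions are
#' ranked by descending score (ties broken by ascending input index), and
#' the precisions at the ranks of the positives are averaged.  This is
#' conservative for rare positives, where trapezoidal interpolation
#' inflates the area.
#'
#' @inheritParams auc_score
#' @return The AUPR in (0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  npos <- sum(labels == 1)
  if (npos == 0) stop("AUPR requires at least one positive label")
  ord <- order(scores, decreasing = TRUE)    # stable: ties keep input order
  lab <- labels[ord]
  prec_at <- cumsum(lab) / seq_along(lab)
  sum(prec_at[lab == 1]) / npos
}

#' Pairwise cross-validation folds for an interaction matrix
#'
#' Shuffles all `m * n` drug-target pairs with a seeded uniform
#' permutation and splits them into `k` contiguous chunks whose sizes
#' differ by at most one.  Each fold's training matrix is `Y` with the
#' fold's test pairs set to 0, so masked positives look like unobserved
#' pairs during training.
#'
#' @param Y An [as_interaction_matrix()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` folds, each a list with `fold_index` (0-based),
#'   `test_pairs` (two-column index matrix, drug then target) and
#'   `Y_train` (the masked interaction matrix).
#' @export
make_folds <- function(Y, k = 10L, seed = 1L) {
  m <- nrow(Y); n <- ncol(Y)
  total <- m * n
  if (k < 2L) stop("k must be at least 2")
  if (k > total) stop("more folds than drug-target pairs")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  perm <- sample.int(total)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  sizes <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- c(0L, cumsum(sizes))
  lapply(seq_len(k), function(f) {
    idx <- perm[(bounds[f] + 1L):bounds[f + 1L]]
    pairs <- cbind(drug = (idx - 1L) %% m + 1L,
                   target = (idx - 1L) %/% m + 1L)
    Ytr <- unclass_matrix(as.matrix(Y))
    Ytr[pairs] <- 0
    list(fold_index = f - 1L, test_pairs = pairs,
         Y_train = structure(Ytr, class = c("interaction_matrix", "matrix",
                                            "array")))
  })
}

# replace the profile-derived members of a similarity triple with
# similarities recomputed from the given (masked) interaction matrix
refresh_profile_sims <- function(sims, Y, space) {
  lapply(sims, function(s) {
    src <- attr(s, "source")
    if (identical(src, "cosine")) profile_cosine(Y, space)
    else if (identical(src, "jaccard")) profile_jaccard(Y, space)
    else s
  })
}

#' Cross-validated-AUC reward surface for the weight search
#'
#' Builds the reward used by the Q-learning search inside one outer fold.
#' In `"inner-validation"` mode (default, leak-free) `n_splits` seeded
#' stratified 10% splits of the fold's training pairs are held out: for
#' each weight state the two similarity triples are fused and, for every
#' split, NRLMF is trained on the training matrix with that split's pairs
#' masked and scored on them; the reward is the mean AUC across splits.
#' Averaging over repeated splits matters because the search takes an
#' argmax over hundreds of memoized rewards, and a single small
#' validation split makes that argmax chase validation noise rather than
#' the fusion-weight signal.  In `"paper-mode"` the model is trained on
#' the full fold training matrix and rewarded with the AUC on the *outer*
#' test pairs; this replicates a protocol in which the searched weights
#' see test labels, and a loud warning is emitted.
#'
#' @param Y_train The fold's masked interaction matrix.
#' @param drug_sims,target_sims Lists of three similarity matrices.
#' @param test_pairs The outer fold's test pairs (used only in
#'   `"paper-mode"`).
#' @param Y_full The unmasked interaction matrix (labels for
#'   `"paper-mode"` scoring).
#' @param control An [nrlmf_control()].
#' @param reward_mode `"inner-validation"` or `"paper-mode"`.
#' @param inner_fraction Fraction of training pairs held out per inner
#'   validation split.
#' @param n_splits Number of repeated inner splits averaged per state.
#' @param seed Integer seed (inner splits and NRLMF initialization).
#' @return A memoizing [reward_environment()].
#' @export
make_nrlmf_reward <- function(Y_train, drug_sims, target_sims,
                              test_pairs = NULL, Y_full = NULL,
                              control = nrlmf_control(),
                              reward_mode = c("inner-validation",
                                              "paper-mode"),
                              inner_fraction = 0.1, n_splits = 5L,
                              seed = 1L) {
  reward_mode <- match.arg(reward_mode)
  m <- nrow(Y_train); n <- ncol(Y_train)

  if (reward_mode == "inner-validation") {
    Ym <- unclass_matrix(as.matrix(Y_train))
    pos <- which(Ym == 1)
    neg <- which(Ym == 0)
    if (!is.null(test_pairs)) {
      # never draw inner validation cells from the outer test pairs
      test_lin <- (test_pairs[, 2L] - 1L) * m + test_pairs[, 1L]
      pos <- setdiff(pos, test_lin)
      neg <- setdiff(neg, test_lin)
    }
    if (length(pos) == 0L) {
      stop("cannot build a stratified inner validation split: no positives")
    }
    n_avail <- length(pos) + length(neg)
    n_inner <- max(2L, round(inner_fraction * n_avail))
    n_pos <- max(1L, min(length(pos),
                         round(n_inner * length(pos) / n_avail)))
    n_neg <- max(1L, min(length(neg), n_inner - n_pos))
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    splits <- lapply(seq_len(n_splits), function(s) {
      inner <- c(pos[sample.int(length(pos), n_pos)],
                 neg[sample.int(length(neg), n_neg)])
      Y_inner <- Ym
      Y_inner[inner] <- 0
      list(idx = inner, labels = Ym[inner],
           Y_fit = structure(Y_inner,
                             class = c("interaction_matrix", "matrix",
                                       "array")))
    })
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  } else {
    warning("paper-mode reward: the weight search is scored on the outer ",
            "test fold, so test labels influence the learned weights",
            immediate. = TRUE)
    if (is.null(test_pairs) || is.null(Y_full)) {
      stop("paper-mode requires test_pairs and Y_full")
    }
    splits <- list(list(idx = test_pairs,
                        labels = unclass_matrix(as.matrix(Y_full))[test_pairs],
                        Y_fit = Y_train))
  }
  for (sp in splits) {
    if (all(sp$labels == 1) || all(sp$labels == 0)) {
      stop("reward split contains a single class; AUC reward undefined")
    }
  }
  # profile-derived similarities are recomputed from each split's training
  # matrix so the scored labels never feed the similarity graph
  for (i in seq_along(splits)) {
    splits[[i]]$ds <- refresh_profile_sims(drug_sims, splits[[i]]$Y_fit, "drug")
    splits[[i]]$ts <- refresh_profile_sims(target_sims, splits[[i]]$Y_fit,
                                           "target")
  }

  # when no split recomputes profile similarities, the fused matrices and
  # their neighborhood Laplacians are shared across splits
  static_sims <- all(vapply(splits, function(sp)
    identical(sp$ds, splits[[1L]]$ds) && identical(sp$ts, splits[[1L]]$ts),
    logical(1)))
  reward_environment(function(s) {
    w <- as.numeric(s) / 10
    Ld <- Lt <- Sd <- St <- NULL
    if (static_sims) {
      Sd <- fuse_similarities(splits[[1L]]$ds, w[1:3])
      St <- fuse_similarities(splits[[1L]]$ts, w[4:6])
      Ld <- build_knn_laplacian(Sd, min(control$K, m - 1L))
      Lt <- build_knn_laplacian(St, min(control$K, n - 1L))
    }
    aucs <- vapply(seq_along(splits), function(i) {
      sp <- splits[[i]]
      if (!static_sims) {
        Sd <<- fuse_similarities(sp$ds, w[1:3])
        St <<- fuse_similarities(sp$ts, w[4:6])
        Ld <- Lt <- NULL
      }
      fit <- nrlmf(sp$Y_fit, Sd, St, control, seed = seed + i,
                   L_d = Ld, L_t = Lt)
      P <- predict(fit)
      auc_score(P[sp$idx], sp$labels)
    }, numeric(1))
    mean(aucs)
  })
}

#' Fit the full Q-learning weighted fusion NRLMF model
#'
#' The end-to-end procedure: all drug-target pairs are split into `k`
#' cross-validation folds; within each fold the profile-derived
#' similarities are recomputed from the masked training matrix, a tabular
#' Q-learning search over the 1296-state weight grid finds the fusion
#' weights that maximize a cross-validated AUC reward, the two similarity
#' triples are fused with the best weights, NRLMF is fitted on the fold's
#' training matrix, and the held-out pairs are scored with AUC and AUPR.
#'
#' @param Y An [as_interaction_matrix()].
#' @param drug_sims,target_sims Lists of up to three similarity matrices
#'   per space.  Members tagged `"cosine"`/`"jaccard"` are recomputed from
#'   the training matrix inside every fold (set
#'   `recompute_profiles = FALSE` to keep them fixed); if fewer than three
#'   are supplied, the triple is completed with profile cosine and Jaccard
#'   similarities.
#' @param control An [nrlmf_control()].
#' @param q_control A [qlearn_control()].
#' @param k Number of folds.
#' @param seed Master seed; folds, inner splits, the Q-learning runs and
#'   all NRLMF initializations derive from it.
#' @param reward_mode Passed to [make_nrlmf_reward()].
#' @param inner_splits Number of repeated inner validation splits averaged
#'   by the reward (passed to [make_nrlmf_reward()]).
#' @param weights Optional fixed six-weight vector (values in tenths or on
#'   \[0, 1\]); when supplied the Q-learning search is skipped -- this is
#'   how the equal-weight baseline is run.
#' @param recompute_profiles Recompute cosine/Jaccard members per fold.
#' @return An object of class `"qlnrlmf"`: `per_fold` (data frame with
#'   fold, auc, aupr, the six best weights and
#'   `distinct_states_visited`), `mean_auc`, `mean_aupr`, `folds`,
#'   `searches` (the per-fold `"qlearn"` objects, `NULL` under fixed
#'   weights), `call`.
#' @export
qlnrlmf <- function(Y, drug_sims, target_sims,
                    control = nrlmf_control(),
                    q_control = qlearn_control(),
                    k = 10L, seed = 1L,
                    reward_mode = c("inner-validation", "paper-mode"),
                    inner_splits = 5L,
                    weights = NULL,
                    recompute_profiles = TRUE) {
  reward_mode <- match.arg(reward_mode)
  drug_sims <- complete_triple(drug_sims, Y, "drug")
  target_sims <- complete_triple(target_sims, Y, "target")
  check_alignment(Y, drug_sims, target_sims)

  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != 6L) stop("weights must have six components")
    if (max(weights) <= 1) weights <- weights * 10
    if (abs(sum(weights[1:3]) - 10) > 1e-9 ||
        abs(sum(weights[4:6]) - 10) > 1e-9) {
      stop("each weight triple must sum to 1")
    }
  }

  folds <- make_folds(Y, k = k, seed = seed)
  Y_full <- unclass_matrix(as.matrix(Y))
  per_fold <- vector("list", k)
  searches <- vector("list", k)

  for (f in seq_len(k)) {
    fold <- folds[[f]]
    fold_seed <- (seed * 1000L + f) %% .Machine$integer.max
    Ytr <- fold$Y_train

    ds <- if (recompute_profiles) refresh_profile_sims(drug_sims, Ytr, "drug")
          else drug_sims
    ts <- if (recompute_profiles) refresh_profile_sims(target_sims, Ytr, "target")
          else target_sims

    if (is.null(weights)) {
      env <- make_nrlmf_reward(Ytr, ds, ts,
                               test_pairs = fold$test_pairs, Y_full = Y,
                               control = control, reward_mode = reward_mode,
                               n_splits = inner_splits, seed = fold_seed)
      search <- q_learn(env, q_control, seed = fold_seed)
      searches[[f]] <- search
      w <- search$best_state / 10
      visited <- search$distinct_states_visited
    } else {
      w <- weights / 10
      visited <- 0L
    }

    Sd <- fuse_similarities(ds, w[1:3])
    St <- fuse_similarities(ts, w[4:6])
    fit <- nrlmf(Ytr, Sd, St, control, seed = fold_seed)
    P <- predict(fit)
    scores <- P[fold$test_pairs]
    labels <- Y_full[fold$test_pairs]
    per_fold[[f]] <- data.frame(
      fold = f, auc = auc_score(scores, labels),
      aupr = aupr_score(scores, labels),
      alpha = w[1], beta = w[2], gamma = w[3],
      x = w[4], y = w[5], z = w[6],
      distinct_states_visited = visited)
  }

  per_fold <- do.call(rbind, per_fold)
  structure(list(per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_aupr = mean(per_fold$aupr),
                 folds = folds, searches = searches,
                 k = k, seed = seed, control = control,
                 q_control = q_control, reward_mode = reward_mode,
                 fixed_weights = weights,
                 call = match.call()),
            class = "qlnrlmf")
}

#' Equal-weight fusion baseline
#'
#' Runs the identical cross-validation pipeline as [qlnrlmf()] but with
#' the fusion weights fixed at (1/3, 1/3, 1/3) in both spaces and no
#' Q-learning search.  Because 1/3 is off the 0.1 search grid the triple
#' is represented exactly, not snapped to the grid.
#'
#' @inheritParams qlnrlmf
#' @return A `"qlnrlmf"` object.
#' @export
qlnrlmf_equal_weights <- function(Y, drug_sims, target_sims,
                                  control = nrlmf_control(),
                                  k = 10L, seed = 1L,
                                  recompute_profiles = TRUE) {
  qlnrlmf(Y, drug_sims, target_sims, control = control, k = k, seed = seed,
          weights = c(1, 1, 1, 1, 1, 1) * (10 / 3),
          recompute_profiles = recompute_profiles)
}

complete_triple <- function(sims, Y, space) {
  if (inherits(sims, "similarity_matrix")) sims <- list(sims)
  if (length(sims) > 3L) stop("at most three similarity matrices per space")
  if (length(sims) < 3L) {
    have <- vapply(sims, function(s) attr(s, "source") %||% "other",
                   character(1))
    if (!"cosine" %in% have && length(sims) < 3L) {
      sims <- c(sims, list(profile_cosine(Y, space)))
    }
    if (!"jaccard" %in% have && length(sims) < 3L) {
      sims <- c(sims, list(profile_jaccard(Y, space)))
    }
  }
  if (length(sims) != 3L) {
    stop("could not complete the ", space, " similarity triple")
  }
  sims
}

check_alignment <- function(Y, drug_sims, target_sims) {
  for (s in drug_sims) {
    if (!is.null(rownames(Y)) && !identical(rownames(s), rownames(Y))) {
      stop("drug similarity ids do not match the interaction matrix rows")
    }
  }
  for (s in target_sims) {
    if (!is.null(colnames(Y)) && !identical(rownames(s), colnames(Y))) {
      stop("target similarity ids do not match the interaction matrix columns")
    }
  }
  invisible(TRUE)
}

#' @export
print.qlnrlmf <- function(x, ...) {
  cat("Q-learning weighted fusion NRLMF cross-validation\n")
  cat(sprintf("  %d folds, seed %d, reward mode %s\n",
              x$k, x$seed,
              if (is.null(x$fixed_weights)) x$reward_mode
              else "fixed weights (no search)"))
  cat(sprintf("  mean AUC  %.4f\n  mean AUPR %.4f\n",
              x$mean_auc, x$mean_aupr))
  invisible(x)
}

#' @export
summary.qlnrlmf <- function(object, ...) {
  object
}

#' Plot per-episode mean reward across folds
#'
#' @param x A `"qlnrlmf"` object produced with the Q-learning search.
#' @param ... Passed to [matplot()].
#' @export
plot.qlnrlmf <- function(x, ...) {
  tr <- lapply(x$searches, function(s) s$episode_avg_rewards)
  tr <- tr[!vapply(tr, is.null, logical(1))]
  if (!length(tr)) stop("no Q-learning traces to plot (fixed weights run)")
  graphics::matplot(do.call(cbind, tr), type = "l", lty = 1,
                    xlab = "episode", ylab = "mean reward", ...)
  invisible(x)
}

#' Write per-fold cross-validation results as CSV
#'
#' Columns: fold, auc, aupr, the six fusion weights and the number of
#' distinct weight states evaluated by the search.
#'
#' @param x A `"qlnrlmf"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cv_results <- function(x, path) {
  utils::write.csv(x$per_fold, path, row.names = FALSE)
  invisible(path)
}
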