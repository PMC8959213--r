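# Fusion-weight search space: each space (drug, target) carries three
# weights on the 0.1 grid, strictly inside (0, 1), summing to 1.  Weights
# are stored as integer tenths so that states have exact keys.

#' Enumerate all valid fusion-weight states
#'
#' A state holds six weights in tenths: \eqn{(\alpha, \beta, \gamma)} for
#' the drug similarity triple and \eqn{(x, y, z)} for the target triple.
#' Each component lies strictly between 0 and 1 on the 0.1 grid and each
#' triple sums to 1, giving 36 triples per space and 1296 joint states.
#' States are returned in lexicographic order of the six tenth-integers.
#'
#' @return A 1296 x 6 integer matrix of tenths with columns
#'   `alpha, beta, gamma, x, y, z`.
#' @export
enumerate_states <- function() {
  g <- expand.grid(k = 1:8, j = 1:8, i = 1:8)   # i slowest for lexicographic
  triples <- as.matrix(g[, c("i", "j", "k")])
  triples <- triples[rowSums(triples) == 10L, , drop = FALSE]
  nt <- nrow(triples)
  joint <- cbind(triples[rep(seq_len(nt), each = nt), , drop = FALSE],
                 triples[rep(seq_len(nt), times = nt), , drop = FALSE])
  colnames(joint) <- c("alpha", "beta", "gamma", "x", "y", "z")
  storage.mode(joint) <- "integer"
  joint
}

state_key <- function(s) paste(s, collapse = ":")

#' The 18 fusion-weight actions
#'
#' An action is `(a, b, c, -(b+c))` with side `a` selecting the drug
#' (`a = 0`) or target (`a = 1`) triple and deltas `b, c` in
#' `{-0.1, 0, 0.1}` applied to the first two weights of that triple, the
#' third weight absorbing `-(b+c)` so the simplex sum is preserved.  The
#' full 2 x 3 x 3 = 18 product is kept, including the two no-ops.
#'
#' @return An 18 x 3 integer matrix (columns `a`, `b`, `c`, with `b`, `c`
#'   in tenths) in canonical order.
#' @export
action_space <- function() {
  g <- expand.grid(c = -1:1, b = -1:1, a = 0:1)
  acts <- as.matrix(g[, c("a", "b", "c")])
  storage.mode(acts) <- "integer"
  rownames(acts) <- NULL
  acts
}

#' Apply an action to a weight state
#'
#' Adds the deltas `(b, c, -(b+c))` to the drug triple if `a = 0` or the
#' target triple if `a = 1`.  If any resulting weight would leave the open
#' interval (0, 1) the move is invalid: the state is returned unchanged
#' with `valid = FALSE` (the caller feeds back reward 0).
#'
#' @param s Integer state vector of six tenths.
#' @param act Integer action vector `(a, b, c)`.
#' @return List with `state` (six tenths) and `valid` (logical).
#' @examples
#' s <- c(3L, 3L, 4L, 3L, 3L, 4L)
#' apply_action(s, c(0L, 1L, 1L))$state  # (4,4,2 | 3,3,4)
#' @export
apply_action <- function(s, act) {
  s <- as.integer(s)
  deltas <- as.integer(c(act[2L], act[3L], -(act[2L] + act[3L])))
  idx <- if (act[1L] == 0L) 1:3 else 4:6
  s2 <- s
  s2[idx] <- s2[idx] + deltas
  if (any(s2[idx] <= 0L) || any(s2[idx] >= 10L)) {
    list(state = s, valid = FALSE)
  } else {
    list(state = s2, valid = TRUE)
  }
}

#' Reward environment over the weight simplex
#'
#' Wraps a deterministic reward surface `f(state) -> [0, 1]` with
#' memoization and evaluation accounting: each distinct state is evaluated
#' at most once, so when `f` fits an NRLMF model the number of model fits
#' equals the number of distinct states visited.  Used both with the real
#' cross-validated-AUC reward ([make_nrlmf_reward()]) and with injected
#' test surfaces.
#'
#' @param f Function taking a six-tenths integer state vector and
#'   returning a scalar reward in \[0, 1\].
#' @return An environment with functions `reward(s)`, `n_evaluated()`,
#'   `evaluated_rewards()` (named vector keyed by state).
#' @export
reward_environment <- function(f) {
  memo <- new.env(parent = emptyenv())
  count <- 0L
  env <- new.env(parent = emptyenv())
  env$reward <- function(s) {
    key <- state_key(s)
    if (exists(key, envir = memo, inherits = FALSE)) {
      return(get(key, envir = memo, inherits = FALSE))
    }
    r <- unname(f(s))
    if (!is.finite(r)) stop("reward surface returned a non-finite value")
    assign(key, r, envir = memo)
    count <<- count + 1L
    r
  }
  env$n_evaluated <- function() count
  env$evaluated_rewards <- function() {
    keys <- ls(memo)
    stats::setNames(vapply(keys, function(k) memo[[k]], numeric(1)), keys)
  }
  env
}

#' Tabular Q-value update
#'
#' The standard off-policy update
#' \deqn{Q(s,a) \leftarrow Q(s,a) + \alpha [r + \gamma \max_{a'} Q(s',a')
#'       - Q(s,a)]}
#' applied in place to a Q-table stored as a dense states x actions
#' matrix.
#'
#' @param Q Numeric matrix (1296 x 18) of Q-values.
#' @param si,ai Row (state) and column (action) indices of the update.
#' @param r Observed reward.
#' @param si2 Row index of the successor state.
#' @param lr Learning rate in (0, 1].
#' @param discount Discount factor in \[0, 1\].
#' @return The updated Q matrix.
#' @export
q_update <- function(Q, si, ai, r, si2, lr, discount) {
  Q[si, ai] <- Q[si, ai] +
    lr * (r + discount * max(Q[si2, ]) - Q[si, ai])
  Q
}

#' Configuration for the Q-learning weight search
#'
#' @param episodes Number of episodes.
#' @param steps_per_episode Steps per episode.
#' @param epsilon_start,epsilon_end Exploration rate, annealed linearly
#'   across episodes (`epsilon_end <= epsilon_start`).
#' @param lr Learning rate in (0, 1].
#' @param discount Discount factor in \[0, 1\].
#' @param initial_state `"random"` (a fresh uniform-random valid state per
#'   episode) or a fixed six-tenths integer vector.
#' @return A list of class `"qlearn_control"`.
#' @export
qlearn_control <- function(episodes = 5000, steps_per_episode = 20,
                           epsilon_start = 0.5, epsilon_end = 0.02,
                           lr = 0.1, discount = 0.9,
                           initial_state = "random") {
  stopifnot(episodes >= 1, steps_per_episode >= 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_end >= 0, epsilon_end <= epsilon_start,
            lr > 0, lr <= 1, discount >= 0, discount <= 1)
  structure(list(episodes = as.integer(episodes),
                 steps_per_episode = as.integer(steps_per_episode),
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 lr = lr, discount = discount,
                 initial_state = initial_state),
            class = "qlearn_control")
}

#' Tabular Q-learning over the fusion-weight simplex
#'
#' Runs epsilon-greedy tabular Q-learning on the 1296-state weight grid.
#' Each step proposes an action; invalid moves (weights leaving (0, 1))
#' receive reward 0 and leave the state unchanged, otherwise the reward of
#' the successor state is queried from the (memoizing) environment.  The
#' best state is the argmax over all states whose reward was ever
#' evaluated, which is also how the search cost is accounted: the number
#' of distinct states evaluated is the number of NRLMF fits the
#' environment performed.
#'
#' @param env A [reward_environment()].
#' @param control A [qlearn_control()].
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return An object of class `"qlearn"` with components `Q` (the
#'   state x action value matrix), `best_state`, `best_reward`,
#'   `episode_avg_rewards`, `epsilon_trace`, `distinct_states_visited`,
#'   `states_until_best`, `states`, `actions`.
#' @export
q_learn <- function(env, control = qlearn_control(), seed = 1L) {
  states <- enumerate_states()
  acts <- action_space()
  ns <- nrow(states); na <- nrow(acts)
  sidx <- stats::setNames(seq_len(ns),
                          apply(states, 1L, paste, collapse = ":"))
  Q <- matrix(0, ns, na)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  eps_sched <- if (control$episodes > 1) {
    seq(control$epsilon_start, control$epsilon_end,
        length.out = control$episodes)
  } else control$epsilon_start

  # transition tables: successor state index and validity per state/action
  trans <- matrix(0L, ns, na)
  valid <- matrix(FALSE, ns, na)
  for (si in seq_len(ns)) {
    for (ai in seq_len(na)) {
      mv <- apply_action(states[si, ], acts[ai, ])
      valid[si, ai] <- mv$valid
      trans[si, ai] <- if (mv$valid) unname(sidx[state_key(mv$state)]) else si
    }
  }

  avg_rewards <- numeric(control$episodes)
  rloc <- rep(NA_real_, ns)        # rewards seen so far, by state index
  states_until_best <- 0L
  best_running <- -Inf
  lr <- control$lr; disc <- control$discount

  fixed_start <- if (!identical(control$initial_state, "random")) {
    k <- state_key(as.integer(control$initial_state))
    if (is.na(sidx[k])) stop("initial_state is not a valid weight state")
    unname(sidx[k])
  } else NA_integer_

  for (ep in seq_len(control$episodes)) {
    epsilon <- eps_sched[ep]
    si <- if (is.na(fixed_start)) sample.int(ns, 1L) else fixed_start
    ep_total <- 0
    for (step in seq_len(control$steps_per_episode)) {
      ai <- if (stats::runif(1) < epsilon) {
        sample.int(na, 1L)
      } else {
        which.max(Q[si, ])                  # ties: first action wins
      }
      if (!valid[si, ai]) {
        r <- 0
        si2 <- si
      } else {
        si2 <- trans[si, ai]
        r <- rloc[si2]
        if (is.na(r)) {
          r <- env$reward(states[si2, ])
          rloc[si2] <- r
          if (r > best_running) {
            best_running <- r
            states_until_best <- env$n_evaluated()
          }
        }
      }
      Q[si, ai] <- Q[si, ai] + lr * (r + disc * max(Q[si2, ]) - Q[si, ai])
      si <- si2
      ep_total <- ep_total + r
    }
    avg_rewards[ep] <- ep_total / control$steps_per_episode
  }

  rewards <- env$evaluated_rewards()
  # argmax over every state evaluated; ties resolved to the
  # lexicographically smallest state for determinism
  ord <- order(-rewards, names(rewards), method = "radix")
  best_key <- names(rewards)[ord[1L]]
  best_reward <- unname(rewards[ord[1L]])
  if (states_until_best == 0L) states_until_best <- length(rewards)

  structure(list(Q = Q,
                 best_state = states[sidx[best_key], ],
                 best_reward = best_reward,
                 episode_avg_rewards = avg_rewards,
                 epsilon_trace = eps_sched,
                 distinct_states_visited = env$n_evaluated(),
                 states_until_best = states_until_best,
                 states = states, actions = acts,
                 control = control, seed = seed),
            class = "qlearn")
}

#' @export
print.qlearn <- function(x, ...) {
  w <- x$best_state / 10
  cat("Q-learning fusion-weight search\n")
  cat(sprintf("  episodes: %d x %d steps, lr %g, discount %g\n",
              x$control$episodes, x$control$steps_per_episode,
              x$control$lr, x$control$discount))
  cat(sprintf("  best weights: drug (%.1f, %.1f, %.1f), target (%.1f, %.1f, %.1f)\n",
              w[1], w[2], w[3], w[4], w[5], w[6]))
  cat(sprintf("  best reward %.4f after evaluating %d of %d states\n",
              x$best_reward, x$distinct_states_visited, nrow(x$states)))
  invisible(x)
}

#' Brute-force search over all weight states
#'
#' Evaluates the reward of every enumerated state and returns the argmax,
#' with ties resolved to the lexicographically smallest state.  Serves as
#' the exhaustive baseline the Q-learning search is compared against: it
#' always costs exactly 1296 evaluations.
#'
#' @param env A [reward_environment()].
#' @return List with `best_state`, `best_reward` and `evaluations`
#'   (the total state count).
#' @export
brute_force_search <- function(env) {
  states <- enumerate_states()
  best_i <- 1L
  best_r <- -Inf
  for (i in seq_len(nrow(states))) {
    r <- env$reward(states[i, ])
    if (r > best_r) {            # strict: first (lexicographic) max kept
      best_r <- r
      best_i <- i
    }
  }
  list(best_state = states[best_i, ], best_reward = best_r,
       evaluations = nrow(states))
}

#' Follow the greedy policy of a learned Q-table
#'
#' From `start`, repeatedly takes the argmax action (ties: first action in
#' canonical order) until the state stops changing, the table offers no
#' positive-valued action, or `max_steps` transitions have been taken
#' (which also bounds greedy cycles).
#'
#' @param fit A `"qlearn"` object.
#' @param start Six-tenths integer state vector.
#' @param max_steps Transition bound.
#' @return The final six-tenths state vector.
#' @export
greedy_policy_state <- function(fit, start, max_steps = 100L) {
  sidx <- stats::setNames(seq_len(nrow(fit$states)),
                          apply(fit$states, 1L, paste, collapse = ":"))
  si <- unname(sidx[state_key(as.integer(start))])
  if (is.na(si)) stop("start is not a valid weight state")
  for (step in seq_len(max_steps)) {
    qs <- fit$Q[si, ]
    if (max(qs) <= 0) break                 # nothing learned from here
    ai <- which.max(qs)
    mv <- apply_action(fit$states[si, ], fit$actions[ai, ])
    si2 <- unname(sidx[state_key(mv$state)])
    if (si2 == si) break                    # fixed point
    si <- si2
  }
  fit$states[si, ]
}

#' Write the reward/convergence trace of a Q-learning run as CSV
#'
#' Columns: `episode`, `mean_reward`, `epsilon`.
#'
#' @param fit A `"qlearn"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reward_trace <- function(fit, path) {
  df <- data.frame(episode = seq_along(fit$episode_avg_rewards),
                   mean_reward = fit$episode_avg_rewards,
                   epsilon = fit$epsilon_trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a learned Q-table as TSV
#'
#' One row per state-action pair with a nonzero value: the six state
#' tenths, the action triple and the Q-value.
#'
#' @param fit A `"qlearn"` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qtable <- function(fit, path) {
  nz <- which(fit$Q != 0, arr.ind = TRUE)
  df <- cbind(as.data.frame(fit$states[nz[, 1L], , drop = FALSE]),
              as.data.frame(fit$actions[nz[, 2L], , drop = FALSE]),
              q = fit$Q[nz])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
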