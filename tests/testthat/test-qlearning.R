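test_that("state enumeration covers exactly the strictly interior 0.1 grid", {
  st <- enumerate_states()
  expect_equal(nrow(st), 1296)
  # 36 strictly positive tenth-triples summing to 10 per simplex
  triples <- unique(st[, 1:3, drop = FALSE])
  expect_equal(nrow(triples), 36)
  expect_true(all(st >= 1 & st <= 8))
  expect_true(all(rowSums(st[, 1:3]) == 10))
  expect_true(all(rowSums(st[, 4:6]) == 10))
  # brute-force count oracle: enumerate all tenth-triples directly
  cnt <- 0
  for (i in 1:9) for (j in 1:9) {
    k <- 10 - i - j
    if (k >= 1 && k <= 9) cnt <- cnt + 1
  }
  expect_equal(nrow(triples), cnt)
  # lexicographic ordering of the six tenths
  keys <- apply(st, 1, function(s) paste(s, collapse = ""))
  expect_identical(keys, sort(keys))
  # membership examples
  expect_true(any(apply(st, 1, identical, y = c(alpha = 3L, beta = 3L,
                                                gamma = 4L, x = 3L,
                                                y = 3L, z = 4L))))
  expect_false(any(st == 0))
})

test_that("the action space is the full 18-action product", {
  acts <- action_space()
  expect_equal(nrow(acts), 18)
  expect_setequal(unique(acts[, "a"]), c(0L, 1L))
  expect_true(all(acts[, c("b", "c")] >= -1 & acts[, c("b", "c")] <= 1))
  expect_equal(nrow(unique(acts)), 18)
})

test_that("actions reproduce the worked transition and reject boundary moves", {
  s <- c(3L, 3L, 4L, 3L, 3L, 4L)
  mv <- apply_action(s, c(0L, 1L, 1L))      # deltas (+0.1, +0.1, -0.2)
  expect_true(mv$valid)
  expect_equal(mv$state, c(4L, 4L, 2L, 3L, 3L, 4L))

  # the same deltas on the target side
  mv2 <- apply_action(s, c(1L, 1L, 1L))
  expect_equal(mv2$state, c(3L, 3L, 4L, 4L, 4L, 2L))

  # no-op actions leave any state unchanged
  expect_equal(apply_action(s, c(0L, 0L, 0L))$state, s)
  expect_true(apply_action(s, c(1L, 0L, 0L))$valid)

  # a weight would hit 0: invalid, state unchanged
  mv3 <- apply_action(c(1L, 1L, 8L, 3L, 3L, 4L), c(0L, -1L, 0L))
  expect_false(mv3$valid)
  expect_equal(mv3$state, c(1L, 1L, 8L, 3L, 3L, 4L))

  # a weight would hit 1 (third component takes -(b+c))
  mv4 <- apply_action(c(1L, 1L, 8L, 3L, 3L, 4L), c(0L, -1L, -1L))
  expect_false(mv4$valid)
})

test_that("valid transitions stay inside the enumerated state space", {
  st <- enumerate_states()
  acts <- action_space()
  keys <- apply(st, 1, paste, collapse = ":")
  withr::with_seed(5, picks <- sample(nrow(st), 60))
  for (i in picks) {
    for (ai in seq_len(nrow(acts))) {
      mv <- apply_action(st[i, ], acts[ai, ])
      expect_true(paste(mv$state, collapse = ":") %in% keys)
      expect_equal(sum(mv$state[1:3]), 10L)
      expect_equal(sum(mv$state[4:6]), 10L)
    }
  }
})

test_that("Q-update reproduces the tabular update rule by substitution", {
  Q <- matrix(0, 3, 18)
  Q2 <- q_update(Q, 1, 2, r = 0.8, si2 = 2, lr = 0.1, discount = 0.9)
  expect_equal(Q2[1, 2], 0.08)
  expect_equal(sum(Q2 != 0), 1)

  Q3 <- matrix(0.5, 2, 18)
  Q3 <- q_update(Q3, 1, 1, r = 1, si2 = 2, lr = 0.1, discount = 0.9)
  expect_equal(Q3[1, 1], 0.5 + 0.1 * (1 + 0.9 * 0.5 - 0.5))  # 0.595

  Q4 <- matrix(0.3, 2, 18)
  expect_equal(q_update(Q4, 1, 1, 1, 2, lr = 0, discount = 0.9), Q4)
})

test_that("reward environments memoize and count distinct evaluations", {
  calls <- 0
  env <- reward_environment(function(s) {
    calls <<- calls + 1
    s[1] / 10
  })
  s <- c(3L, 3L, 4L, 3L, 3L, 4L)
  expect_equal(env$reward(s), 0.3)
  expect_equal(env$reward(s), 0.3)
  expect_equal(calls, 1)
  expect_equal(env$n_evaluated(), 1)
  env$reward(c(4L, 3L, 3L, 3L, 3L, 4L))
  expect_equal(env$n_evaluated(), 2)
  expect_length(env$evaluated_rewards(), 2)
})

test_that("brute force evaluates every state once and breaks ties lexicographically", {
  env <- reward_environment(function(s) 0.7)
  res <- brute_force_search(env)
  expect_equal(res$evaluations, 1296)
  expect_equal(env$n_evaluated(), 1296)
  expect_equal(res$best_state, enumerate_states()[1, ])
  expect_equal(res$best_reward, 0.7)

  # planted unique argmax is found
  target <- c(2L, 5L, 3L, 4L, 4L, 2L)
  env2 <- reward_environment(function(s) {
    if (all(s == target)) 0.95 else 0.1
  })
  res2 <- brute_force_search(env2)
  expect_equal(unname(res2$best_state), target)
  expect_equal(res2$best_reward, 0.95)
})

test_that("Q-learning finds the optimum of injected deterministic surfaces", {
  cfg <- qlearn_control(episodes = 1500, steps_per_episode = 20,
                        epsilon_start = 1, epsilon_end = 0.05)
  surfaces <- list(
    ridge = function(s) 1 - abs(s[1] / 10 - 0.5) - abs(s[4] / 10 - 0.5),
    corner = function(s) (s[1] + s[4]) / 20,          # max at (8,1,1 | 8,1,1)
    planted = function(s) {
      if (all(s == c(2L, 5L, 3L, 4L, 4L, 2L))) 0.95 else
        0.3 + 0.02 * (s[2] / 10)
    })
  for (nm in names(surfaces)) {
    env_q <- reward_environment(surfaces[[nm]])
    env_b <- reward_environment(surfaces[[nm]])
    fit <- q_learn(env_q, cfg, seed = 0)
    bf <- brute_force_search(env_b)
    expect_equal(fit$best_reward, bf$best_reward, tolerance = 1e-12,
                 label = paste("reward on surface", nm))
    if (nm != "ridge") {      # ridge has a 16-state tie on each simplex
      expect_equal(fit$best_state, bf$best_state,
                   label = paste("state on surface", nm))
    } else {
      expect_equal(unname(fit$best_state[1]), 5L)
      expect_equal(unname(fit$best_state[4]), 5L)
    }
  }
})

test_that("Q-learning runs are deterministic and bounded", {
  surf <- function(s) (s[1] + 2 * s[5]) / 30
  cfg <- qlearn_control(episodes = 60, steps_per_episode = 10)
  f1 <- q_learn(reward_environment(surf), cfg, seed = 123)
  f2 <- q_learn(reward_environment(surf), cfg, seed = 123)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$best_state, f2$best_state)
  expect_identical(f1$episode_avg_rewards, f2$episode_avg_rewards)

  expect_length(f1$episode_avg_rewards, 60)
  expect_true(all(f1$episode_avg_rewards >= 0 & f1$episode_avg_rewards <= 1))
  expect_lte(f1$distinct_states_visited, 1296)
  expect_lte(f1$states_until_best, f1$distinct_states_visited)
  expect_gte(f1$best_reward, 0)
})

test_that("a fixed initial state is honored and validated", {
  surf <- function(s) s[1] / 10
  cfg <- qlearn_control(episodes = 5, steps_per_episode = 5,
                        epsilon_start = 0, epsilon_end = 0,
                        initial_state = c(3L, 3L, 4L, 3L, 3L, 4L))
  fit <- q_learn(reward_environment(surf), cfg, seed = 1)
  expect_s3_class(fit, "qlearn")
  cfg_bad <- qlearn_control(episodes = 5, steps_per_episode = 5,
                            initial_state = c(5L, 5L, 0L, 3L, 3L, 4L))
  expect_error(q_learn(reward_environment(surf), cfg_bad), "not a valid")
})

test_that("the greedy policy reaches the planted optimum after training", {
  target <- c(2L, 5L, 3L, 4L, 4L, 2L)
  surf <- function(s) {
    if (all(s == target)) 0.95 else 0.3 - 0.01 * sum(abs(s - target))
  }
  start <- c(3L, 3L, 4L, 3L, 3L, 4L)
  fit <- q_learn(reward_environment(surf),
                 qlearn_control(episodes = 800, steps_per_episode = 20,
                                epsilon_start = 1, epsilon_end = 0.05,
                                initial_state = start),
                 seed = 2)
  out <- greedy_policy_state(fit, start = start)
  expect_equal(unname(out), target)

  # an untrained table goes nowhere
  fit$Q[] <- 0
  s0 <- start
  expect_equal(unname(greedy_policy_state(fit, s0)), s0)
  # bounded even if values induce a cycle
  fit$Q[] <- 1
  expect_silent(greedy_policy_state(fit, s0, max_steps = 7))
})

test_that("trace and Q-table exports are well-formed CSV/TSV", {
  surf <- function(s) s[2] / 10
  fit <- q_learn(reward_environment(surf),
                 qlearn_control(episodes = 10, steps_per_episode = 5),
                 seed = 3)
  trace_path <- withr::local_tempfile(fileext = ".csv")
  write_reward_trace(fit, trace_path)
  tr <- read.csv(trace_path)
  expect_named(tr, c("episode", "mean_reward", "epsilon"))
  expect_equal(nrow(tr), 10)

  qt_path <- withr::local_tempfile(fileext = ".tsv")
  write_qtable(fit, qt_path)
  qt <- read.delim(qt_path)
  expect_named(qt, c("alpha", "beta", "gamma", "x", "y", "z",
                     "a", "b", "c", "q"))
  expect_true(all(qt$q != 0))
})
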