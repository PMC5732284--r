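test_that("policy entropy follows the Shannon form", {
  expect_equal(policy_entropy(rep(1 / 7, 7)), log(7))
  expect_equal(policy_entropy(c(1, rep(0, 6))), 0)
  expect_equal(policy_entropy(c(0.5, 0.5, rep(0, 5))), log(2))
  m <- rbind(rep(1 / 7, 7), c(1, rep(0, 6)))
  expect_equal(policy_entropy(m), c(log(7), 0))
  expect_error(policy_entropy(c(0.5, 0.2)))
})

test_that("softmax policy posterior weights policies by chosen-action value", {
  tr <- sim_session("fixed_policy", seed = 21, policy_id = 7)
  rl <- run_all_policies(tr, learning_params(0.3, 4))
  ps <- softmax_policy_posterior(tr, rl)
  # first trial: all values zero, posterior uniform
  expect_equal(ps$posterior[1, ], rep(1 / 7, 7))
  expect_equal(unname(rowSums(ps$posterior)), rep(1, nrow(tr)))
  expect_true(all(ps$entropy >= 0 & ps$entropy <= log(7) + 1e-12))

  # dominance example: one policy values the chosen action at 10, others 0
  qa <- c(10, rep(0, 6))
  w <- exp(qa - max(qa))
  expect_equal((w / sum(w))[1], exp(10) / (exp(10) + 6), tolerance = 1e-12)

  # missed trials carry the previous posterior forward
  tr2 <- tr
  tr2$action[5] <- "missed"; tr2$reward[5] <- 0
  rl2 <- run_all_policies(tr2, learning_params(0.3, 4))
  ps2 <- softmax_policy_posterior(tr2, rl2)
  expect_equal(ps2$posterior[5, ], ps2$posterior[4, ])
})

test_that("HMM forward filter matches the exhaustive-path oracle", {
  tr_full <- sim_session("fixed_policy", seed = 22, policy_id = 4)
  stay <- 0.9
  for (T_len in c(2, 4, 6)) {
    tr <- tr_full[seq_len(T_len), ]
    rl <- run_all_policies(tr, learning_params(0.35, 3))
    hp <- hmm_policy_posterior(tr, rl, stay_prob = stay)
    em <- emissions_for(tr, rl)
    oracle <- hmm_path_oracle(em, stay)
    expect_equal(hp$posterior[T_len, ], oracle$posterior, tolerance = 1e-9)
    # the predictive mixture reproduces the exact joint path likelihood
    logL <- mixture_session_likelihood(hp$predictive, rl, tr)
    expect_equal(logL, log(oracle$likelihood), tolerance = 1e-9)
  }
})

test_that("HMM filter limits behave as expected", {
  tr <- sim_session("fixed_policy", seed = 23, policy_id = 2)[1:40, ]
  tr$trial_index <- seq_len(40)
  rl <- run_all_policies(tr, learning_params(0.3, 3))
  # identical emissions across policies keep the posterior uniform
  rl_flat <- lapply(rl, function(r) { r$p_action <- rep(0.5, 40); r })
  hp <- hmm_policy_posterior(tr, rl_flat, stay_prob = 0.9)
  expect_equal(hp$posterior, matrix(1 / 7, 40, 7))
  # near-uniform transitions reduce to an emission-only filter
  hp2 <- hmm_policy_posterior(tr, rl, stay_prob = 1 / 7 + 1e-9)
  em <- emissions_for(tr, rl)
  expected <- t(apply(em, 1, function(e) e / sum(e)))
  expect_equal(hp2$posterior, expected, tolerance = 1e-6)
})

test_that("polynomial smoothing is exact on low-degree inputs", {
  n <- 64
  flat <- matrix(rep(seq(0.1, 0.7, length.out = 7), each = n), n, 7)
  sm <- smooth_posterior(flat, degree = 5)
  expect_equal(sm, flat, tolerance = 1e-8)
  # a linear trajectory is inside the degree-5 family
  lin <- matrix(seq(0, 1, length.out = n), n, 7)
  lin[, 2] <- rev(lin[, 2])
  expect_equal(smooth_posterior(lin, 5), lin, tolerance = 1e-8)
  # adding a constant to every series cannot change the argmax
  set.seed(1)
  post <- matrix(runif(7 * n), n, 7)
  post <- post / rowSums(post)
  cp1 <- current_policy(smooth_posterior(post, 5))
  cp2 <- current_policy(smooth_posterior(post + 0.3, 5))
  expect_equal(cp1, cp2)
  expect_error(smooth_posterior(post[1:5, ], 5))
})

test_that("current policy takes the argmax with dimensionality tie-break", {
  sm <- matrix(0.1, 4, 7)
  sm[, 5] <- 0.9
  expect_equal(current_policy(sm), rep(5L, 4))
  # exact tie between a 2-feature and the 3-feature policy: lower wins
  tie <- matrix(0.1, 2, 7); tie[, 4] <- 0.8; tie[, 7] <- 0.8
  expect_equal(current_policy(tie), c(4L, 4L))
  # tie among equal dimensionality: lower id wins
  tie2 <- matrix(0.1, 1, 7); tie2[, 5] <- 0.8; tie2[, 6] <- 0.8
  expect_equal(current_policy(tie2), 5L)
})

test_that("transition detection marks every change point", {
  expect_equal(nrow(detect_transitions(rep(7L, 30))), 0L)
  tv <- detect_transitions(c(rep(4L, 10), rep(7L, 10)))
  expect_equal(tv$trial_index, 11L)
  expect_equal(tv$from_policy, 4L)
  expect_equal(tv$to_policy, 7L)
  alt <- detect_transitions(rep(c(1L, 2L), 5))
  expect_equal(nrow(alt), 9L)
  expect_error(detect_transitions(3L))
})

test_that("strategy classification follows first/last quarter dimensionality", {
  expect_equal(classify_strategy(rep(7L, 100)), "only_3d")
  expect_equal(classify_strategy(c(rep(4L, 50), rep(7L, 50))), "2d_to_3d")
  expect_equal(classify_strategy(c(rep(7L, 50), rep(5L, 50))), "3d_to_2d")
  expect_equal(classify_strategy(rep(6L, 40)), "only_2d")
  expect_equal(classify_strategy(rep(2L, 100)), "one_dim")
  # a one-dimensional first quarter fits none of the four main classes
  expect_equal(classify_strategy(c(rep(1L, 30), rep(4L, 35), rep(7L, 35))),
               "other")
  expect_error(classify_strategy(integer(0)))
})

test_that("mixture likelihood reduces correctly in degenerate cases", {
  tr <- toy_session(rep("pass", 12))
  rl <- run_all_policies(tr, learning_params(0.3, 2))
  post_u <- matrix(1 / 7, 12, 7)
  # all policies predict 1/2, so the mixture is 1/2 per trial
  expect_equal(mixture_session_likelihood(post_u, rl, tr), 12 * log(0.5))
  # all mass on one policy reduces to that policy's likelihood
  tr2 <- sim_session("fixed_policy", seed = 24, policy_id = 3)[1:50, ]
  tr2$trial_index <- seq_len(50)
  rl2 <- run_all_policies(tr2, learning_params(0.3, 2))
  post_d <- matrix(0, 50, 7); post_d[, 3] <- 1
  expect_equal(mixture_session_likelihood(post_d, rl2, tr2),
               session_log_likelihood(rl2[[3]]$p_action, tr2))
})
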