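test_that("information criteria follow their definitions", {
  expect_equal(aic(0, 0), 0)
  expect_equal(bic(0, 0, 100), 0)
  expect_equal(aic(-100, 3), 206)
  expect_equal(bic(-100, 3, 256), 3 * log(256) + 200)
  expect_error(bic(-1, 2, 0))
})

test_that("model fits are deterministic and internally consistent", {
  tr <- sim_session("fixed_policy", seed = 41, policy_id = 7)
  f1 <- fit_model(tr, "policy7_noise")
  f2 <- fit_model(tr, "policy7_noise")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$logL, f2$logL)
  # stored criteria satisfy their identities
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$logL)
  expect_equal(f1$bic, f1$k * log(f1$n) - 2 * f1$logL)
  expect_equal(f1$k, 3L)
  expect_equal(f1$n, sum(tr$action != "missed"))
})

test_that("uninformative data drive the inverse temperature to chance", {
  tr <- sim_session("random", seed = 42)
  pf <- fit_policy(tr, get_policy(7))
  expect_gte(pf$logL, 256 * log(0.5) - 1e-6)   # chance is always attainable
  expect_lt(pf$logL, 256 * log(0.5) + 8)       # and barely improvable
  expect_lt(pf$params$beta * 10, 5)            # beta near its lower bound
})

test_that("the lapse model never fits worse than its nested pure model", {
  # policy7_noise nests the plain full-policy model at epsilon = 0
  for (seed in 401:410) {
    tr <- sim_session("fixed_policy", seed = seed, policy_id = 7)
    base <- fit_policy(tr, get_policy(7))
    noisy <- fit_model(tr, "policy7_noise")
    expect_gte(noisy$logL, base$logL - 1e-4)
  }
})

test_that("paired model comparison handles regular and degenerate cohorts", {
  mk <- function(aics) lapply(aics, function(a)
    structure(list(model = "m", logL = -a / 2, k = 2, n = 256,
                   aic = a, bic = a), class = "model_fit"))
  a <- mk(c(250, 260, 240, 255))
  b <- mk(c(255, 270, 241, 260))
  cmp <- compare_models(a, b, "aic")
  expect_lt(cmp$mean_diff, 0)
  expect_false(cmp$degenerate)
  expect_equal(cmp$df, 3)
  # identical fit sets: zero difference, p = 1, flagged degenerate
  cmp2 <- compare_models(a, a, "aic")
  expect_equal(cmp2$mean_diff, 0)
  expect_equal(cmp2$p, 1)
  expect_true(cmp2$degenerate)
  # constant non-zero difference: undefined t, flagged
  b3 <- mk(c(255, 265, 245, 260))
  cmp3 <- compare_models(a, b3, "aic")
  expect_true(cmp3$degenerate)
  expect_true(is.na(cmp3$t))
  expect_error(compare_models(a, b[1:3], "aic"))
})

test_that("transition-entropy test contrasts transition trials with all trials", {
  mk_sess <- function(ent, idx) list(entropy = ent,
                                     transitions = data.frame(trial_index = idx))
  s1 <- mk_sess(c(2, 2, 1, 1), c(2L))
  s2 <- mk_sess(c(1.9, 1.2, 1.8, 1.0), c(3L))
  res <- transition_entropy_test(list(s1, s2))
  expect_equal(res$n_included, 2)
  expect_gt(res$mean_diff, 0)
  # sessions without transitions are excluded but counted
  s3 <- mk_sess(rep(1, 4), integer(0))
  res2 <- transition_entropy_test(list(s1, s2, s3))
  expect_equal(res2$n_excluded, 1)
  # a single usable session is not a cohort
  expect_error(transition_entropy_test(list(s1, s3)))
  # constant posteriors give zero difference
  s4 <- mk_sess(rep(1.5, 6), c(2L, 4L))
  s5 <- mk_sess(rep(1.5, 6), c(3L))
  res3 <- transition_entropy_test(list(s4, s5))
  expect_equal(res3$mean_diff, 0)
  expect_equal(res3$p, 1)
})

test_that("transition-timing regression recovers exact and null structure", {
  lin <- data.frame(trial_index = 1:20, entropy = 2 - 0.05 * (1:20))
  res <- suppressWarnings(transition_timing_regression(lin))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, -0.05)
  set.seed(12)
  shuf <- data.frame(trial_index = 1:200, entropy = runif(200))
  res2 <- transition_timing_regression(shuf)
  expect_lt(res2$r_squared, 0.05)
  expect_error(transition_timing_regression(lin[1:2, ]))
  degen <- data.frame(trial_index = rep(5, 10), entropy = runif(10))
  expect_error(transition_timing_regression(degen))
})

test_that("likelihood-performance correlation matches OLS structure", {
  logL <- c(-150, -120, -100, -90, -170)
  exact <- suppressWarnings(
    likelihood_performance_correlation(logL, 2 * logL + 400))
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  const <- likelihood_performance_correlation(logL, rep(100, 5))
  expect_equal(const$r_squared, 0)
})
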