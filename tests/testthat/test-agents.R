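test_that("the random agent is a stateless fair coin", {
  set.seed(1)
  ag <- random_agent()
  stim <- list(shape = "square", colour = "blue", pattern = "vertical")
  acts <- replicate(2000, ag$choose(stim))
  expect_true(all(acts %in% c("go", "pass")))
  expect_lt(abs(mean(acts == "go") - 0.5), 0.05)
})

test_that("fixed-policy agents learn their own state-space", {
  cfg <- task_config(seed = 51)
  set.seed(51)
  ag <- fixed_policy_agent(get_policy(7), learning_params(0.3, 5))
  res <- play_session(ag, cfg)
  q <- ag$q()
  st <- enumerate_stimuli()
  am <- st[st$category == "all_match", ]
  pen <- st[st$category == "penalised_nonmatch", ]
  s_am <- project_states(am, get_policy(7))
  s_pen <- project_states(pen, get_policy(7))
  # deterministic contingencies are learned with the right signs
  expect_true(all(q[s_am, 1] > 5))
  expect_true(all(q[s_pen, 1] < 0))
  expect_gt(res$final_score, 156)
})

test_that("exploring agents reduce to fixed-policy agents at switch_prob 0", {
  cfg <- task_config(seed = 52)
  set.seed(52)
  ag <- exploring_transfer_agent(learning_params(0.25, 5), switch_prob = 0,
                                 start_policy = 6L)
  play_session(ag, cfg)
  expect_equal(length(ag$switches()), 0L)
  expect_equal(ag$active_policy(), 6L)
})

test_that("exploring agents make sparse, early-biased transitions", {
  counts <- integer(0); medians <- numeric(0)
  for (s in 61:72) {
    cfg <- task_config(seed = s)
    set.seed(s)
    ag <- exploring_transfer_agent(learning_params(0.25, 5))
    play_session(ag, cfg)
    sw <- ag$switches()
    counts <- c(counts, length(sw))
    if (length(sw) > 0) medians <- c(medians, stats::median(sw))
  }
  expect_lt(mean(counts), 15)           # a handful, not constant churn
  expect_gt(mean(counts > 0), 0.5)      # but exploration does happen
  expect_lt(stats::median(medians), 128) # concentrated in the first half
})

test_that("scheduled transfer agents follow their schedule exactly", {
  sched <- c(rep(4L, 100), rep(7L, 156))
  cfg <- task_config(seed = 53)
  set.seed(53)
  ag <- scheduled_transfer_agent(sched, learning_params(0.25, 5), "inherited")
  res <- play_session(ag, cfg)
  expect_equal(nrow(res$trials), 256L)
  expect_equal(nrow(ag$q()), 8L)  # ends on the full policy's table
})

test_that("exploration schedules are seeded, early-biased step functions", {
  s1 <- make_exploration_schedule(256, 3, seed = 9)
  s2 <- make_exploration_schedule(256, 3, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 256L)
  expect_true(all(s1 %in% 1:7))
  tv <- which(diff(s1) != 0) + 1L
  expect_lte(length(tv), 3L)
  s3 <- make_exploration_schedule(256, 0, seed = 1)
  expect_equal(length(unique(s3)), 1L)
})

test_that("cohort simulation is reproducible and fully manifested", {
  cfg <- task_config()
  configs <- list(agent_config("random", seed = 71),
                  agent_config("fixed_policy", seed = 72, policy_id = 7),
                  agent_config("exploring_transfer", seed = 73))
  sim1 <- simulate_cohort(configs, cfg)
  sim2 <- simulate_cohort(configs, cfg)
  expect_identical(sim1$sessions, sim2$sessions)
  expect_identical(sim1$manifest, sim2$manifest)
  expect_equal(nrow(sim1$manifest), 3L)
  expect_true(all(c("kind", "alpha", "beta", "init_rule", "seed",
                    "final_score") %in% names(sim1$manifest)))
  # the manifest score matches the session it describes
  expect_equal(sim1$manifest$final_score, sim1$scores)
  expect_equal(sapply(sim1$sessions, function(s) sum(s$reward)), sim1$scores)
  # duplicate seeds are refused; empty cohorts are legal
  expect_error(simulate_cohort(list(agent_config("random", seed = 1),
                                    agent_config("random", seed = 1)), cfg))
  empty <- simulate_cohort(list(), cfg)
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("cohort files round-trip through the session format", {
  cfg <- task_config()
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(list(agent_config("fixed_policy", seed = 81,
                                           policy_id = 4)), cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "session_001.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_session(file.path(dir, "session_001.tsv"))
  expect_equal(back, sim$sessions[[1L]])
})

test_that("the mixed cohort template mirrors the study's group structure", {
  configs <- mixed_cohort_configs(seed = 3)
  expect_length(configs, 29L)
  kinds <- vapply(configs, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "exploring_transfer"), 19L)
  expect_equal(sum(kinds == "fixed_policy"), 6L)
  expect_equal(sum(kinds == "random"), 4L)
  expect_false(anyDuplicated(vapply(configs, `[[`, integer(1), "seed")) > 0)
})
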