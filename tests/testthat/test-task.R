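test_that("stimulus enumeration yields 8 distinct categorised stimuli", {
  for (variant in c("pattern_nonmatch", "shape_nonmatch", "colour_nonmatch")) {
    st <- enumerate_stimuli(variant)
    expect_equal(nrow(st), 8L)
    expect_equal(nrow(unique(st[, c("shape", "colour", "pattern")])), 8L)
    # every variant partitions the stimuli 2/2/2/2 across categories
    expect_equal(as.integer(sort(table(st$category))), c(2L, 2L, 2L, 2L))
    # the all-match pair never depends on the variant
    am <- st[st$category == "all_match", ]
    expect_setequal(paste(am$shape, am$colour, am$pattern),
                    c("square blue vertical", "circle yellow horizontal"))
    # each penalised stimulus is one step from an all-match stimulus, and
    # the step is in the variant's named dimension
    pen <- st[st$category == "penalised_nonmatch", ]
    dim_changed <- sub("_nonmatch$", "", variant)
    for (i in 1:2) {
      dists <- vapply(1:2, function(j) {
        sum(vapply(c("shape", "colour", "pattern"),
                   function(f) pen[[f]][i] != am[[f]][j], logical(1)))
      }, numeric(1))
      j <- which.min(dists)
      expect_equal(dists[j], 1)
      differing <- names(which(vapply(c("shape", "colour", "pattern"),
                                      function(f) pen[[f]][i] != am[[f]][j],
                                      logical(1))))
      expect_equal(differing, dim_changed)
    }
  }
  expect_error(enumerate_stimuli("size_nonmatch"))
})

test_that("main-task reward rule matches the design", {
  st <- enumerate_stimuli("pattern_nonmatch")
  bsv <- as.list(st[st$shape == "square" & st$colour == "blue" &
                      st$pattern == "vertical", ])
  bsh <- as.list(st[st$shape == "square" & st$colour == "blue" &
                      st$pattern == "horizontal", ])
  bcv <- as.list(st[st$shape == "circle" & st$colour == "blue" &
                      st$pattern == "vertical", ])
  expect_equal(bsv$category, "all_match")
  expect_equal(bsh$category, "penalised_nonmatch")
  expect_match(bcv$category, "^random_nonmatch")

  cfg <- task_config()
  expect_equal(sample_reward(bsv, "go", cfg), 10)
  expect_equal(sample_reward(bsh, "go", cfg), -10)
  expect_equal(sample_reward(bsv, "pass", cfg), 0)
  expect_error(sample_reward(bsv, "missed", cfg))
  # random category pays +/-10 at one half: Monte-Carlo mean near 0
  set.seed(42)
  draws <- replicate(10000, sample_reward(bcv, "go", cfg))
  expect_true(all(abs(draws) == 10))
  expect_lt(abs(mean(draws)), 0.5)
})

test_that("trial sequences are balanced, seeded shuffles", {
  seq1 <- generate_trial_sequence(task_config(seed = 7))
  expect_equal(nrow(seq1), 256L)
  counts <- table(paste(seq1$shape, seq1$colour, seq1$pattern))
  expect_true(all(counts == 32L))
  seq2 <- generate_trial_sequence(task_config(seed = 7))
  expect_identical(seq1, seq2)
  seq3 <- generate_trial_sequence(task_config(seed = 8))
  expect_false(identical(seq1$shape, seq3$shape))
  # variant experiment: two extra stages
  seqv <- generate_trial_sequence(task_config("shape_nonmatch",
                                              n_stages = 10, seed = 1))
  expect_equal(nrow(seqv), 320L)
  expect_error(task_config(n_stages = 3, trials_per_stage = 3))
})

test_that("session play-out conserves score and validates agents", {
  cfg <- task_config(seed = 11)
  always_pass <- list(choose = function(s) "pass",
                      observe = function(s, a, r) NULL)
  res <- play_session(always_pass, cfg)
  expect_equal(res$final_score, 0)
  expect_true(all(res$trials$reward == 0))

  set.seed(3)
  res2 <- play_session(random_agent(), cfg)
  # score conservation: 10 * (#go wins - #go losses)
  go <- res2$trials$action == "go"
  expect_equal(res2$final_score,
               10 * (sum(res2$trials$reward[go] > 0) -
                       sum(res2$trials$reward[go] < 0)))
  bad_agent <- list(choose = function(s) "left",
                    observe = function(s, a, r) NULL)
  expect_error(play_session(bad_agent, cfg), "invalid action")
})

test_that("random-responder null matches the session decomposition", {
  cfg <- task_config()
  # category-count sampler agrees with full play-outs in mean and spread
  set.seed(5)
  direct <- replicate(300, {
    cfg2 <- cfg
    cfg2$seed <- NULL
    play_session(random_agent(), cfg2)$final_score
  })
  decomposed <- polexplore:::simulate_null_scores(cfg, 20000)
  expect_lt(abs(mean(decomposed)), 3)          # symmetric null
  expect_lt(abs(mean(direct)), 25)
  # analytic null SD is sqrt(64*25 + 64*25 + 128*50) = 98
  expect_lt(abs(stats::sd(decomposed) - 98), 4)
  expect_lt(abs(stats::sd(direct) - 98), 15)
  expect_true(all(decomposed %% 10 == 0))
})

test_that("chance-level cutoff behaves as an empirical quantile", {
  cfg <- task_config()
  expect_lt(abs(chance_level_cutoff(cfg, 20000, 0.5, seed = 1)), 5)
  one <- chance_level_cutoff(cfg, 1, 0.95, seed = 2)
  set.seed(2)
  expect_equal(one, polexplore:::simulate_null_scores(cfg, 1))
  expect_error(chance_level_cutoff(cfg, 100, 1.5))
})
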