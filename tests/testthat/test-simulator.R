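test_that("invalid population configs are rejected with the offending fields", {
  expect_error(population_config(arm_probabilities = c(0.5, 0.4, 0.0)),
               "summing to 1", class = "spacedselect_config_error")
  expect_error(population_config(q = 0.5), "q must be",
               class = "spacedselect_config_error")
  expect_error(population_config(horizon_days = 0), "horizon",
               class = "spacedselect_config_error")
  err <- tryCatch(population_config(n0_median = -1, true_alpha = 2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "n0_median")
  expect_match(err, "true_alpha")
})

test_that("a zero session rate produces an empty trial", {
  sim <- simulate_trial(population_config(
    n_learners = 5, n_items = 5, session_rate = 0, seed = 1))
  expect_equal(nrow(sim$log), 0L)
})

test_that("the same seed reproduces the log byte-for-byte", {
  cfg <- population_config(n_learners = 25, n_items = 10,
                           horizon_days = 10, seed = 77)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_review_log(simulate_trial(cfg)$log, p1)
  write_review_log(simulate_trial(cfg)$log, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed does not
  cfg2 <- population_config(n_learners = 25, n_items = 10,
                            horizon_days = 10, seed = 78)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_review_log(simulate_trial(cfg2)$log, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("session counts follow the Poisson arrival process", {
  n_learners <- 500
  horizon <- 30
  sim <- simulate_trial(population_config(
    n_learners = n_learners, n_items = 10, session_rate = 1,
    horizon_days = horizon, dropout_hazard = 0, session_size_mean = 2,
    seed = 13))
  n_sessions <- nrow(dplyr::distinct(tibble::as_tibble(sim$log),
                                     session_id))
  mu <- n_learners * horizon
  expect_lt(abs(n_sessions - mu), 3 * sqrt(mu))
})

test_that("arm assignment is categorical, seeded, and balanced", {
  expect_equal(unique(assign_arms(50, c(1, 0, 0), seed = 3)), "select")
  labels <- assign_arms(30000, rep(1 / 3, 3), seed = 1)
  counts <- table(labels)
  sigma <- sqrt(30000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 10000) < 3 * sigma))
  expect_identical(labels, assign_arms(30000, rep(1 / 3, 3), seed = 1))
  expect_error(assign_arms(10, c(0.5, 0.4)), "summing to 1")
})

test_that("replaying a simulated log confirms the stored ground truth", {
  sim <- simulate_trial(population_config(
    n_learners = 20, n_items = 8, horizon_days = 15, seed = 21))
  expect_true(replay_log(sim$log, sim$truth))

  # flipping one recall bit corrupts every later latent rate of that pair
  events <- tibble::as_tibble(sim$log)
  pair_sizes <- dplyr::count(events, learner_id, question_id)
  busy <- pair_sizes[pair_sizes$n >= 3, ][1, ]
  idx <- which(events$learner_id == busy$learner_id &
                 events$question_id == busy$question_id)[1]
  events$recall[idx] <- 1L - events$recall[idx]
  corrupted <- review_log(events, metadata = attr(sim$log, "metadata"))
  expect_error(replay_log(corrupted, sim$truth),
               class = "spacedselect_integrity_error")

  # empty log replays trivially
  empty_sim <- simulate_trial(population_config(
    n_learners = 3, n_items = 3, session_rate = 0, seed = 1))
  expect_true(replay_log(empty_sim$log, empty_sim$truth))
})

test_that("first-ever exposures are exchangeable across arms at baseline", {
  sim <- simulate_trial(population_config(
    n_learners = 400, n_items = 30, horizon_days = 20, seed = 17))
  firsts <- recall_observations(sim$log)$first_reviews
  arms <- sim$truth$arms[firsts$learner_id]
  tab <- table(arms, firsts$recall)
  # randomization guarantees identical first-exposure outcome rates
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("learner dropout shortens usage spans", {
  base <- population_config(n_learners = 150, n_items = 10,
                            horizon_days = 40, dropout_hazard = 0,
                            seed = 33)
  heavy <- population_config(n_learners = 150, n_items = 10,
                             horizon_days = 40, dropout_hazard = 0.15,
                             seed = 33)
  span <- function(sim) {
    median(tapply(sim$log$time, sim$log$learner_id,
                  function(t) max(t) - min(t)))
  }
  expect_lt(span(simulate_trial(heavy)), span(simulate_trial(base)) / 2)
})

test_that("the estimated-mode scheduler runs and stays reproducible", {
  cfg <- population_config(n_learners = 15, n_items = 8, horizon_days = 12,
                           scheduler = "estimated", refit_every = 5,
                           seed = 55)
  s1 <- suppressWarnings(simulate_trial(cfg))
  s2 <- suppressWarnings(simulate_trial(cfg))
  expect_equal(tibble::as_tibble(s1$log), tibble::as_tibble(s2$log))
})

test_that("a policy override runs every learner under one policy but keeps labels", {
  cfg <- population_config(n_learners = 40, n_items = 10, horizon_days = 10,
                           policy_override = "random", seed = 3)
  sim <- simulate_trial(cfg)
  expect_setequal(unique(sim$log$arm), c("select", "difficulty", "random"))
  expect_true(replay_log(sim$log, sim$truth))
})
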