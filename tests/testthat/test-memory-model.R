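test_that("recall probability follows the exponential forgetting curve", {
  expect_equal(recall_probability(0.1, 0), 1)
  expect_equal(recall_probability(log(2) / 3, 3), 0.5)
  expect_equal(recall_probability(0.2, 5), exp(-1))
  # strictly decreasing in delta for positive rates
  deltas <- seq(0, 30, by = 0.5)
  expect_true(all(diff(recall_probability(0.3, deltas)) < 0))
  expect_error(recall_probability(-0.1, 1), ">= 0")
  expect_error(recall_probability(0.1, -1), ">= 0")
})

test_that("the multiplicative update matches hand-computed trajectories", {
  params <- hlr_params(c(item = 1), alpha = 0.2, beta = 0.5)
  st <- memory_state(1)
  st <- update_forgetting_rate(st, 1, params)
  st <- update_forgetting_rate(st, 1, params)
  st <- update_forgetting_rate(st, 0, params)
  expect_equal(st$n, 1 * 0.8 * 0.8 * 1.5)   # = 0.96
  expect_equal(st$successes, 2L)
  expect_equal(st$failures, 1L)

  p2 <- hlr_params(c(i = 1), alpha = 0.5, beta = 1)
  expect_equal(update_forgetting_rate(memory_state(1), 1, p2)$n, 0.5)
  expect_equal(update_forgetting_rate(memory_state(1), 0, p2)$n, 2)
  expect_error(update_forgetting_rate(memory_state(1), 2, p2), "0 or 1")
})

test_that("predicted_rate equals the folded update over random histories", {
  withr::local_seed(101)
  params <- hlr_params(setNames(runif(5, 0.05, 2), paste0("q", 1:5)),
                       alpha = 0.25, beta = 0.7)
  for (rep in 1:100) {
    item <- sample(names(params$n0), 1)
    s <- sample(0:8, 1)
    f <- sample(0:8, 1)
    # fold the per-review update in a random interleaving
    st <- memory_state(params$n0[[item]])
    for (r in sample(c(rep(1, s), rep(0, f)))) {
      st <- update_forgetting_rate(st, r, params)
    }
    pred <- predicted_rate(
      tibble::tibble(item_id = item, successes_before = s,
                     failures_before = f), params)
    expect_equal(unname(pred), st$n, tolerance = 1e-12)
  }
  # edge cases
  expect_equal(
    unname(predicted_rate(tibble::tibble(item_id = "q1",
                                         successes_before = 0,
                                         failures_before = 0), params)),
    params$n0[["q1"]])
  p0 <- hlr_params(params$n0, alpha = 0, beta = 0)
  expect_equal(
    unname(predicted_rate(tibble::tibble(item_id = "q2",
                                         successes_before = 7,
                                         failures_before = 3), p0)),
    params$n0[["q2"]])
  expect_error(predicted_rate(tibble::tibble(item_id = "nope",
                                             successes_before = 0,
                                             failures_before = 0), params),
               class = "spacedselect_lookup_error")
})

test_that("fitting a single item at its half-life matches a 1-D grid oracle", {
  # observations all at the delta where true m = 0.5, balanced outcomes:
  # the squared-error-optimal rate satisfies n * delta = ln 2
  delta <- 4
  obs <- tibble::tibble(item_id = "q", delta = delta,
                        successes_before = 0L, failures_before = 0L,
                        recall = rep(c(0L, 1L), 50))
  grid <- seq(0.01, 2, by = 1e-4)
  sse <- vapply(grid, function(n) sum((obs$recall - exp(-n * delta))^2),
                numeric(1))
  n_oracle <- grid[which.min(sse)]
  expect_equal(n_oracle * delta, log(2), tolerance = 1e-2)

  fit <- fit_hlr(obs, l2 = 1e-8)
  expect_equal(unname(fit$n0[["q"]]) * delta, log(2), tolerance = 1e-3)
  expect_equal(unname(fit$n0[["q"]]), n_oracle, tolerance = 1e-3)
})

test_that("the optimizer does not increase the objective and improves on truth-scale data", {
  sim <- simulate_trial(population_config(
    n_learners = 40, n_items = 10, horizon_days = 20, seed = 5))
  obs <- recall_observations(sim$log)$observations
  fit <- fit_hlr(obs)
  expect_lte(attr(fit, "objective"), attr(fit, "initial_objective"))
  expect_equal(attr(fit, "convergence"), 0)
})

test_that("heavy regularization shrinks the multipliers and pools the item rates", {
  withr::local_seed(7)
  obs <- tibble::tibble(
    item_id = rep(c("a", "b"), each = 40),
    delta = runif(80, 1, 10),
    successes_before = sample(0:3, 80, replace = TRUE),
    failures_before = sample(0:3, 80, replace = TRUE),
    recall = sample(0:1, 80, replace = TRUE))
  fit <- fit_hlr(obs, l2 = 1e6)
  expect_lt(fit$alpha, 1e-3)
  expect_lt(fit$beta, 1e-3)
  expect_lt(abs(log(fit$n0[["a"]]) - log(fit$n0[["b"]])), 1e-3)
})

test_that("single-delta constant-outcome items are flagged as weakly identified", {
  obs <- tibble::tibble(item_id = "only", delta = 3,
                        successes_before = 0L, failures_before = 0L,
                        recall = rep(1L, 10))
  expect_warning(fit_hlr(obs), "weakly identified")
})

test_that("estimates move toward truth as the sample grows", {
  err <- vapply(c(60, 240), function(n_learners) {
    sim <- simulate_trial(population_config(
      n_learners = n_learners, n_items = 12, horizon_days = 40,
      dropout_hazard = 0, seed = 99))
    obs <- recall_observations(sim$log)$observations
    fit <- suppressWarnings(fit_hlr(obs))
    abs(fit$alpha - 0.3) + abs(fit$beta - 0.6)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.15)
})

test_that("parameter JSON round-trips", {
  params <- hlr_params(c(q1 = 0.25, q2 = 1.5), alpha = 0.31, beta = 0.62,
                       l2 = 1e-3)
  path <- withr::local_tempfile(fileext = ".json")
  write_hlr_params(params, path)
  back <- read_hlr_params(path)
  expect_equal(back$n0, params$n0)
  expect_equal(back$alpha, params$alpha)
  expect_equal(back$beta, params$beta)
})

test_that("initial-rate estimation covers unseen items via the global median", {
  log <- review_log(dplyr::bind_rows(
    make_events("u1", "q1", c(0, 4, 9), c(1, 1, 0)),
    make_events("u2", "q1", c(0, 6), c(0, 1)),
    make_events("u1", "q2", c(0, 5, 11), c(1, 0, 1)),
    make_events("u3", "lonely", 2, 1)))    # never re-reviewed
  for (method in c("fitted", "empirical")) {
    n0 <- suppressWarnings(estimate_initial_rates(log, method = method))
    expect_setequal(names(n0), c("lonely", "q1", "q2"))
    expect_true(all(n0 > 0))
    expect_equal(n0[["lonely"]], median(n0[c("q1", "q2")]))
  }
})
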