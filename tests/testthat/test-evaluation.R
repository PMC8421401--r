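test_that("empirical forgetting rate inverts the forgetting curve at the test", {
  expect_equal(empirical_forgetting_rate(7, 1, 0.01), -log(0.99) / 7)
  expect_equal(empirical_forgetting_rate(7, 0, 0.01), -log(0.01) / 7)
  # recalled tests always imply slower forgetting than forgotten ones
  for (eps in c(0.001, 0.1, 0.49)) {
    expect_lt(empirical_forgetting_rate(3, 1, eps),
              empirical_forgetting_rate(3, 0, eps))
  }
  # vanishes with the interval for recalled items
  expect_lt(empirical_forgetting_rate(1e6, 1), 1e-7)
  expect_lt(empirical_forgetting_rate(1e6, 1),
            empirical_forgetting_rate(1e3, 1))
  expect_error(empirical_forgetting_rate(0, 1), "delta")
  expect_error(empirical_forgetting_rate(1, 1, epsilon = 0.7), "epsilon")
})

test_that("half-life is inversely proportional to the forgetting rate", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.1) * 2, half_life(0.05))
  expect_equal(half_life(0.0014357), 482.8, tolerance = 1e-3)
  expect_error(half_life(0), "> 0")
})

test_that("sequence summaries take the last review as the test", {
  log <- review_log(dplyr::bind_rows(
    make_events("u", "q", c(0, 3, 10), c(1, 1, 1), arm = "select"),
    make_events("u", "single", 4, 1, arm = "select")))
  summ <- summarize_sequences(build_sequences(log),
                              c(q = 0.2, single = 0.2))
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$n_reviews, 2L)
  expect_equal(summ$T, 10)
  expect_equal(summ$delta_test, 7)
  expect_equal(summ$n_hat, -log(0.99) / 7)
  expect_equal(summ$normalized_rate, summ$n_hat / 0.2)
  expect_equal(summ$half_life, log(2) / summ$n_hat)
  expect_equal(attr(summ, "excluded")[["single_review"]], 1L)
  expect_error(summarize_sequences(build_sequences(log), c(q = 0.2)),
               class = "spacedselect_lookup_error")
})

test_that("summaries plus exclusions conserve the sequences", {
  sim <- simulate_trial(population_config(
    n_learners = 50, n_items = 20, horizon_days = 20, seed = 8))
  seqs <- build_sequences(sim$log)
  summ <- summarize_sequences(seqs, estimate_initial_rates(sim$log))
  expect_equal(nrow(summ) + sum(attr(summ, "excluded")), nrow(seqs))
})

test_that("control bins partition the summaries into at most 18 cells", {
  sim <- simulate_trial(population_config(
    n_learners = 150, n_items = 20, horizon_days = 30, seed = 9))
  summ <- summarize_sequences(build_sequences(sim$log),
                              estimate_initial_rates(sim$log))
  binned <- bin_by_controls(summ, n_reviews_range = 2:7, n_t_bins = 3)
  expect_lte(length(unique(binned$cell)), 18)
  expect_equal(nrow(binned), sum(summ$n_reviews %in% 2:7))
  expect_false(any(is.na(binned$t_bin)))
  # each row in exactly one cell; T within its bin bounds
  expect_true(all(binned$T >= binned$t_lo & binned$T <= binned$t_hi))
  # one T bin keys cells by review count only
  one_bin <- bin_by_controls(summ, 2:7, n_t_bins = 1)
  expect_setequal(unique(one_bin$cell),
                  sprintf("r%d-t1", intersect(2:7, one_bin$n_reviews)))
})

test_that("Mann-Whitney matches the closed 2x2 case and handles identical samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)    # exact enumeration over C(4,2)
  tied <- mann_whitney_u(c(5, 5, 5, 6, 7, 8), c(5, 5, 5, 6, 7, 8))
  expect_gt(tied$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(), 1), "nonempty")
})

test_that("exact Mann-Whitney agrees with exhaustive permutation enumeration", {
  withr::local_seed(2024)
  for (rep in 1:60) {
    nx <- sample(1:6, 1)
    ny <- sample(1:(8 - max(nx, 1)), 1)
    # half the cases carry heavy ties
    pool <- if (rep %% 2) rnorm(nx + ny) else sample(1:3, nx + ny, TRUE)
    x <- pool[seq_len(nx)]
    y <- pool[nx + seq_len(ny)]
    res <- mann_whitney_u(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, mw_enumerate(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches the reference implementation", {
  withr::local_seed(11)
  for (rep in 1:20) {
    x <- rnorm(40)
    y <- rnorm(35, mean = 0.3)
    if (rep %% 2) {
      x <- round(x)      # heavy ties exercise the tie-corrected variance
      y <- round(y)
    }
    res <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE))
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("arm comparison flags a large shift and reports consistent medians", {
  withr::local_seed(4)
  base <- tibble::tibble(
    learner_id = "x", question_id = "q", n_reviews = 2L,
    T = runif(300, 5, 20), delta_test = 1, test_recall = 1L,
    n_hat = 1, n0_hat = 1,
    normalized_rate = c(rlnorm(100), rlnorm(100) * 8, rlnorm(100) * 8),
    half_life = 1, arm = rep(c("select", "random", "difficulty"), each = 100))
  binned <- bin_by_controls(base, 2, n_t_bins = 1)
  cmp <- compare_arms(binned)
  expect_true(all(cmp$contrasts$significant))
  expect_equal(cmp$contrasts$median_select,
               rep(median(base$normalized_rate[base$arm == "select"]), 2))
  expect_equal(cmp$summary$frac_select_lower, 1)
  # a missing arm is skipped, not fatal
  cmp2 <- compare_arms(binned[binned$arm != "difficulty", ])
  skipped <- cmp2$contrasts[cmp2$contrasts$baseline == "difficulty", ]
  expect_true(all(skipped$skipped))
})

test_that("the robust fit agrees with the reference M-estimator", {
  skip_if_not_installed("MASS")
  withr::local_seed(88)
  n <- 150
  X <- cbind(1, runif(n, 0, 30), rbinom(n, 1, 0.4))
  y <- drop(X %*% c(1, -0.02, 0.5)) + rnorm(n, sd = 0.2)
  y[sample(n, 8)] <- y[sample(n, 8)] + 10
  fit <- huber_fit(X, y)
  ref <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-10)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("noiseless data generated from the regression model is recovered exactly", {
  withr::local_seed(6)
  n <- 120
  arm <- sample(c("select", "random", "difficulty"), n, replace = TRUE)
  T <- runif(n, 5, 50)
  truth <- c(c = 2, w_T = -0.04, w_random = 0.5, w_difficulty = 0.3)
  y <- truth["c"] + truth["w_T"] * (T - median(T)) +
    truth["w_random"] * (arm == "random") +
    truth["w_difficulty"] * (arm == "difficulty")
  df <- tibble::tibble(n_reviews = 3L, arm = arm, T = T,
                       normalized_rate = y)
  fit <- fit_eq1(df)
  expect_equal(fit$c, unname(truth["c"]), tolerance = 1e-6)
  expect_equal(fit$w_T, unname(truth["w_T"]), tolerance = 1e-6)
  expect_equal(fit$w_random, unname(truth["w_random"]), tolerance = 1e-6)
  expect_equal(fit$w_difficulty, unname(truth["w_difficulty"]),
               tolerance = 1e-6)
  expect_error(fit_eq1(df[df$arm != "random", ]), "random",
               class = "spacedselect_rank_error")
})

test_that("Huber regression resists gross outliers better than least squares", {
  withr::local_seed(12)
  n <- 200
  arm <- rep(c("select", "random", "difficulty"), length.out = n)
  T <- runif(n, 5, 50)
  truth <- c(c = 1, w_T = -0.03, w_random = 0.4, w_difficulty = 0.2)
  y <- truth["c"] + truth["w_T"] * (T - median(T)) +
    truth["w_random"] * (arm == "random") +
    truth["w_difficulty"] * (arm == "difficulty") + rnorm(n, sd = 0.05)
  out_idx <- sample(n, 10)
  y[out_idx] <- y[out_idx] + 40      # 5% gross outliers
  df <- tibble::tibble(n_reviews = 2L, arm = arm, T = T,
                       normalized_rate = y)
  fit <- fit_eq1(df)
  X <- cbind(1, T - median(T), arm == "random", arm == "difficulty")
  ols <- qr.coef(qr(X), y)
  err_huber <- max(abs(c(fit$c, fit$w_T, fit$w_random, fit$w_difficulty) -
                         unname(truth)))
  err_ols <- max(abs(ols - unname(truth)))
  expect_lt(err_huber, err_ols)
  expect_lt(err_huber, 0.1)
})

test_that("regression coefficient bias shrinks as the sample grows", {
  mean_bias <- vapply(c(120, 4000), function(n) {
    mean(vapply(314:316, function(seed) {
      withr::with_seed(seed, {
        arm <- sample(c("select", "random", "difficulty"), n,
                      replace = TRUE)
        T <- runif(n, 5, 50)
        y <- 2 - 0.04 * (T - median(T)) + 0.5 * (arm == "random") +
          0.3 * (arm == "difficulty") + rnorm(n, sd = 0.4)
        fit <- fit_eq1(tibble::tibble(n_reviews = 2L, arm = arm, T = T,
                                      normalized_rate = y))
        max(abs(c(fit$c - 2, fit$w_T + 0.04, fit$w_random - 0.5,
                  fit$w_difficulty - 0.3)))
      })
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_bias[2], mean_bias[1])
  expect_lt(mean_bias[2], 0.05)
})

test_that("engagement metrics match a hand tally on a six-learner fixture", {
  mk <- function(id, days, arm) {
    dplyr::bind_rows(lapply(seq_along(days), function(i) {
      make_events(id, "q1", days[i], 1, arm = arm,
                  session_id = paste0(id, "-s", i))
    }))
  }
  log <- review_log(dplyr::bind_rows(
    mk("r1", c(0, 5), "random"),        # returns in 4-7 d
    mk("r2", c(0, 1), "random"),        # early stopper
    mk("s1", c(0, 4), "select"),        # returns (boundary, day 4)
    mk("s2", c(0, 7), "select"),        # returns (boundary, day 7)
    mk("s3", c(0, 3, 10), "select"),    # no session in [4, 7]
    mk("d1", c(0, 2, 20), "difficulty")))
  eng <- engagement_metrics(log)
  per_arm <- eng$per_arm
  get <- function(a, col) per_arm[[col]][per_arm$arm == a]
  expect_equal(get("random", "frac_return_4_7"), 1 / 2)
  expect_equal(get("select", "frac_return_4_7"), 2 / 3)
  expect_equal(get("difficulty", "frac_return_4_7"), 0)
  expect_equal(get("random", "frac_early_stop"), 1 / 2)
  expect_equal(get("select", "frac_early_stop"), 0)
  expect_true(all(per_arm$frac_return_4_7 >= 0 &
                    per_arm$frac_return_4_7 <= 1))
  expect_equal(unname(eng$relative_to_random["select"]),
               100 * (2 / 3 / (1 / 2) - 1))
})
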