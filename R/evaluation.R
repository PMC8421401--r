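#' Empirical forgetting rate of a test review
#'
#' A single binary test outcome observed an interval `delta` after the
#' previous review pins the forgetting rate only up to the smoothing
#' constant `epsilon`: the recall probability at test is taken to be
#' `1 - epsilon` when the item was recalled and `epsilon` when it was
#' forgotten, and inverted through the exponential forgetting curve,
#' `n_hat = -log(r_tilde) / delta`. Vectorized.
#'
#' @param delta_test interval preceding the test review, days, `> 0`.
#' @param test_recall 0/1 outcome(s) of the test review.
#' @param epsilon smoothing constant in `(0, 0.5)` (default 0.01).
#' @return empirical forgetting rate(s), 1/day, positive.
#' @export
#' @examples
#' empirical_forgetting_rate(7, 1)   # -log(0.99)/7
#' empirical_forgetting_rate(7, 0)   # -log(0.01)/7
empirical_forgetting_rate <- function(delta_test, test_recall,
                                      epsilon = 0.01) {
  assert_scalar_number(epsilon, "epsilon", lower = 0, upper = 0.5,
                       strict_lower = TRUE)
  if (epsilon >= 0.5) abort("`epsilon` must be < 0.5")
  if (any(!is.finite(delta_test)) || any(delta_test <= 0)) {
    abort("`delta_test` must be > 0")
  }
  if (any(!(test_recall %in% c(0, 1)))) abort("`test_recall` must be 0 or 1")
  r_tilde <- ifelse(test_recall == 1, 1 - epsilon, epsilon)
  -log(r_tilde) / delta_test
}

#' Memory half-life implied by a forgetting rate
#'
#' Time until recall probability decays to one half: `log(2) / n`.
#'
#' @param n_hat forgetting rate(s), 1/day, `> 0`.
#' @return half-life/half-lives in days.
#' @export
half_life <- function(n_hat) {
  if (any(!is.finite(n_hat)) || any(n_hat <= 0)) abort("`n_hat` must be > 0")
  log(2) / n_hat
}

#' Summarize per-(learner, question) review sequences for evaluation
#'
#' The chronologically last review of each pair is its test review. Each
#' pair with at least two reviews yields one record: the number of earlier
#' reviews, the study period `T` (first review to test review), the test
#' interval, the test outcome, the empirical forgetting rate, its
#' normalization by the item's initial-difficulty rate, and the implied
#' half-life. Single-review pairs (and degenerate zero-interval tests) are
#' excluded and counted.
#'
#' @param sequences nested tibble from [build_sequences()].
#' @param n0_map named vector of per-item initial-difficulty rates, e.g.
#'   from [estimate_initial_rates()].
#' @param epsilon smoothing constant for [empirical_forgetting_rate()].
#' @return a tibble with one row per evaluable pair (columns
#'   `learner_id`, `question_id`, `arm`, `n_reviews`, `T`, `delta_test`,
#'   `test_recall`, `n_hat`, `n0_hat`, `normalized_rate`, `half_life`);
#'   exclusion counts in `attr(, "excluded")`.
#' @export
summarize_sequences <- function(sequences, n0_map, epsilon = 0.01) {
  stopifnot(is.data.frame(sequences), "events" %in% names(sequences))
  unknown <- setdiff(unique(sequences$question_id), names(n0_map))
  if (length(unknown) > 0) {
    abort(sprintf("`n0_map` missing item(s): %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "spacedselect_lookup_error")
  }
  single <- sequences$n_events < 2L
  multi <- sequences[!single, , drop = FALSE]
  if (nrow(multi) == 0) {
    out <- tibble::tibble(
      learner_id = character(), question_id = character(), arm = character(),
      n_reviews = integer(), T = double(), delta_test = double(),
      test_recall = integer(), n_hat = double(), n0_hat = double(),
      normalized_rate = double(), half_life = double())
    attr(out, "excluded") <- c(single_review = sum(single),
                               zero_interval = 0L)
    return(out)
  }
  stats_mat <- vapply(multi$events, function(ev) {
    k <- nrow(ev)
    c(T = ev$time[k] - ev$time[1],
      delta_test = ev$time[k] - ev$time[k - 1L],
      test_recall = ev$recall[k])
  }, c(T = 0, delta_test = 0, test_recall = 0))
  arm <- vapply(multi$events, function(ev) ev$arm[[1]], character(1))
  out <- tibble::tibble(
    learner_id = multi$learner_id, question_id = multi$question_id,
    arm = arm, n_reviews = multi$n_events - 1L,
    T = unname(stats_mat["T", ]),
    delta_test = unname(stats_mat["delta_test", ]),
    test_recall = as.integer(unname(stats_mat["test_recall", ])))
  degenerate <- out$delta_test <= 0
  out <- out[!degenerate, , drop = FALSE]
  out$n_hat <- empirical_forgetting_rate(out$delta_test, out$test_recall,
                                         epsilon)
  out$n0_hat <- unname(n0_map[out$question_id])
  out$normalized_rate <- out$n_hat / out$n0_hat
  out$half_life <- half_life(out$n_hat)
  attr(out, "excluded") <- c(single_review = sum(single),
                             zero_interval = sum(degenerate))
  out
}

#' Bin sequence summaries by the control variables
#'
#' Controlled comparison strata: exact number of reviews crossed with
#' within-stratum quantile bins of the study period `T` (terciles by
#' default), so that pairs compared across arms reviewed the item the same
#' number of times over approximately the same period. With reviews
#' restricted to 2..7 and 3 T-bins this yields up to 18 cells, i.e. 36
#' arm contrasts under the two comparisons per cell.
#'
#' @param summaries tibble from [summarize_sequences()].
#' @param n_reviews_range integer vector of review counts to keep
#'   (default `2:7`).
#' @param n_t_bins number of T quantile bins per review stratum
#'   (default 3).
#' @return `summaries` restricted to `n_reviews_range`, with added columns
#'   `t_bin` (integer), `t_lo`, `t_hi` (bin bounds) and `cell` (label);
#'   rows partition into cells.
#' @export
bin_by_controls <- function(summaries, n_reviews_range = 2:7, n_t_bins = 3) {
  stopifnot(n_t_bins >= 1)
  kept <- summaries[summaries$n_reviews %in% n_reviews_range, , drop = FALSE]
  if (nrow(kept) == 0) {
    kept$t_bin <- integer()
    kept$t_lo <- double()
    kept$t_hi <- double()
    kept$cell <- character()
    return(kept)
  }
  kept |>
    dplyr::group_by(.data$n_reviews) |>
    dplyr::group_modify(function(df, key) {
      breaks <- unique(quantile(df$T, probs = seq(0, 1, length.out =
                                                    n_t_bins + 1)))
      if (length(breaks) < 2) breaks <- c(breaks, breaks + 1e-9)
      df$t_bin <- as.integer(cut(df$T, breaks = breaks,
                                 include.lowest = TRUE, labels = FALSE))
      df$t_lo <- breaks[df$t_bin]
      df$t_hi <- breaks[df$t_bin + 1L]
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(cell = sprintf("r%d-t%d", .data$n_reviews, .data$t_bin))
}

#' Mann-Whitney U test with midrank ties and exact small-sample p-values
#'
#' The U statistic is computed from midranks (tie-corrected). The
#' two-sided p-value uses exact enumeration of all label assignments when
#' the combined sample size is at most `exact_limit`, and otherwise the
#' normal approximation with tie-corrected variance (continuity
#' corrected).
#'
#' @param x,y numeric samples (nonempty).
#' @param exact_limit switch to exact enumeration when
#'   `length(x) + length(y) <=` this (default 10).
#' @param correct apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return list with `U` (for the first sample), `p_value` (two-sided),
#'   and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 10, correct = TRUE) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty")
  }
  if (any(!is.finite(c(x, y)))) abort("samples must be finite")
  nx <- length(x)
  ny <- length(y)
  ranks <- rank(c(x, y))           # midranks
  U <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx + ny <= exact_limit) {
    labs <- combn(nx + ny, nx)
    us <- apply(labs, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  n_tot <- nx + ny
  tie_tab <- table(ranks)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n_tot * (n_tot - 1))
  sigma2 <- nx * ny / 12 * ((n_tot + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- U - mu
  if (correct) z <- z - sign(z) * 0.5
  p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
  list(U = U, p_value = p, method = "normal")
}

#' Controlled arm comparisons of the normalized forgetting rate
#'
#' Within every control cell, contrasts the select arm against the random
#' and difficulty arms with two-sided Mann-Whitney U tests, applies a
#' Bonferroni threshold `alpha_level / n_comparisons`, and aggregates the
#' headline quantities: the fraction of contrasts in which the select
#' median is lower, the fraction significantly so, the median relative
#' decrease in median normalized rate, and the median relative increase
#' in median half-life.
#'
#' @param binned tibble from [bin_by_controls()].
#' @param alpha_level family significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor; default `2 *` number of cells.
#' @param value column to compare (default `"normalized_rate"`).
#' @return list with `cells` (per-cell per-arm quantiles), `contrasts`
#'   (one row per cell x baseline arm: U, p, significance, medians,
#'   relative change) and `summary` (headline aggregates).
#' @export
compare_arms <- function(binned, alpha_level = 0.05, n_comparisons = NULL,
                         value = "normalized_rate") {
  stopifnot(value %in% names(binned))
  if (nrow(binned) == 0) abort("no data to compare")
  cells <- binned |>
    dplyr::group_by(.data$cell, .data$n_reviews, .data$t_bin, .data$t_lo,
                    .data$t_hi, .data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = quantile(.data[[value]], 0.25),
      median = median(.data[[value]]),
      q75 = quantile(.data[[value]], 0.75),
      median_half_life = median(.data$half_life),
      .groups = "drop")
  cell_ids <- unique(binned$cell)
  if (is.null(n_comparisons)) n_comparisons <- 2L * length(cell_ids)
  threshold <- alpha_level / n_comparisons

  rows <- list()
  for (cid in cell_ids) {
    sub <- binned[binned$cell == cid, , drop = FALSE]
    sel <- sub[sub$arm == "select", , drop = FALSE]
    for (other in c("random", "difficulty")) {
      oth <- sub[sub$arm == other, , drop = FALSE]
      if (nrow(sel) == 0 || nrow(oth) == 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell = cid, n_reviews = sub$n_reviews[1], baseline = other,
          n_select = nrow(sel), n_baseline = nrow(oth),
          U = NA_real_, p_value = NA_real_, significant = NA,
          median_select = NA_real_, median_baseline = NA_real_,
          rate_decrease = NA_real_, half_life_increase = NA_real_,
          skipped = TRUE)
        next
      }
      test <- mann_whitney_u(sel[[value]], oth[[value]])
      med_s <- median(sel[[value]])
      med_o <- median(oth[[value]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell = cid, n_reviews = sub$n_reviews[1], baseline = other,
        n_select = nrow(sel), n_baseline = nrow(oth),
        U = test$U, p_value = test$p_value,
        significant = test$p_value < threshold & med_s < med_o,
        median_select = med_s, median_baseline = med_o,
        rate_decrease = (med_o - med_s) / med_o,
        half_life_increase = median(sel$half_life) /
          median(oth$half_life) - 1,
        skipped = FALSE)
    }
  }
  contrasts <- dplyr::bind_rows(rows)
  done <- contrasts[!contrasts$skipped, , drop = FALSE]
  summary <- list(
    n_cells = length(cell_ids),
    n_contrasts = nrow(done),
    n_comparisons = n_comparisons,
    threshold = threshold,
    frac_select_lower = mean(done$median_select < done$median_baseline),
    frac_significant = mean(done$significant),
    median_rate_decrease = vapply(
      split(done, done$baseline), function(d) median(d$rate_decrease),
      numeric(1)),
    median_half_life_increase = vapply(
      split(done, done$baseline), function(d) median(d$half_life_increase),
      numeric(1)))
  list(cells = cells, contrasts = contrasts, summary = summary)
}

# ---- robust regression -----------------------------------------------------

#' Huber robust linear regression by iteratively reweighted least squares
#'
#' Minimizes `sum(rho_k(r_i / s))` over the coefficients, where `rho_k` is
#' the Huber loss with threshold `k` on standardized residuals and the
#' scale `s` is re-estimated each iteration as the median absolute
#' residual divided by 0.6745. Iterates weighted least squares with scale
#' re-estimation until the scale stabilizes, then freezes the scale and
#' iterates to convergence, so the returned coefficients minimize the
#' Huber objective at the returned scale.
#'
#' @param X design matrix (including the intercept column).
#' @param y response vector.
#' @param k Huber threshold on standardized residuals (default 1.345,
#'   giving 95% efficiency at the Gaussian model).
#' @param tol convergence tolerance on coefficients (default 1e-10).
#' @param max_iter iteration cap (default 200).
#' @return list with `coefficients`, `scale`, `iterations`, `converged`.
#' @export
huber_fit <- function(X, y, k = 1.345, tol = 1e-10, max_iter = 200L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) > ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("design matrix is rank deficient",
          class = "spacedselect_rank_error")
  }
  beta <- qr.coef(qrX, y)
  s <- NA_real_
  fixed_scale <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    if (!fixed_scale) {
      s_new <- median(abs(r)) / 0.6745
      if (s_new < .Machine$double.eps * max(abs(y), 1)) {
        # residuals (essentially) zero: exact interpolation
        return(list(coefficients = beta, scale = 0, iterations = it,
                    converged = TRUE))
      }
      if (is.finite(s) && abs(s_new - s) < 1e-8 * s) fixed_scale <- TRUE
      else s <- s_new
    }
    w <- pmin(1, k * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (fixed_scale && delta < tol * max(1, max(abs(beta)))) {
      return(list(coefficients = beta, scale = s, iterations = it,
                  converged = TRUE))
    }
  }
  list(coefficients = beta, scale = s, iterations = max_iter,
       converged = FALSE)
}

#' Spacing-effect regression of the normalized forgetting rate
#'
#' For a fixed number of reviews, fits the robust linear model
#' `normalized_rate = c + w_T (T - T_median) + w_difficulty I_difficulty
#' + w_random I_random` with the select arm as the reference level. A
#' negative `w_T` is the spacing effect (more spread-out reviews, slower
#' forgetting); positive arm coefficients mean higher forgetting than
#' under the select policy.
#'
#' @param summaries tibble from [summarize_sequences()] restricted to one
#'   `n_reviews` value (or pass `n_reviews` to subset).
#' @param n_reviews optionally subset `summaries` to this review count.
#' @param k,tol Huber threshold and convergence tolerance, passed to
#'   [huber_fit()].
#' @return a one-row tibble: `n_reviews`, `c`, `w_T`, `w_random`,
#'   `w_difficulty`, `T_median`, `scale`, `n_obs`, `huber_k`.
#' @export
fit_eq1 <- function(summaries, n_reviews = NULL, k = 1.345, tol = 1e-10) {
  df <- summaries
  if (!is.null(n_reviews)) {
    df <- df[df$n_reviews == n_reviews, , drop = FALSE]
  }
  if (length(unique(df$n_reviews)) > 1) {
    abort("`summaries` span several review counts; pass `n_reviews`")
  }
  if (nrow(df) < 10) abort("need at least 10 summaries to fit")
  missing_arms <- setdiff(ARM_LEVELS, unique(df$arm))
  if (length(missing_arms) > 0) {
    abort(sprintf("arm(s) absent from the data: %s",
                  paste(missing_arms, collapse = ", ")),
          class = "spacedselect_rank_error")
  }
  t_median <- median(df$T)
  X <- cbind(intercept = 1,
             T_centered = df$T - t_median,
             I_random = as.numeric(df$arm == "random"),
             I_difficulty = as.numeric(df$arm == "difficulty"))
  fit <- huber_fit(X, df$normalized_rate, k = k, tol = tol)
  tibble::tibble(
    n_reviews = df$n_reviews[1],
    c = unname(fit$coefficients["intercept"]),
    w_T = unname(fit$coefficients["T_centered"]),
    w_random = unname(fit$coefficients["I_random"]),
    w_difficulty = unname(fit$coefficients["I_difficulty"]),
    T_median = t_median, scale = fit$scale, n_obs = nrow(df),
    huber_k = k, converged = fit$converged)
}

#' Per-arm engagement metrics
#'
#' For each learner: whether any session starts within the window 4 to 7
#' days (inclusive) after their first session (short-term retention of the
#' user), and whether their last session falls within 2 days of their
#' first (early dropout). Aggregated per arm, with relative differences
#' against the random arm.
#'
#' @param log a [review_log()].
#' @param return_window two-sided window in days after the first session
#'   (default `c(4, 7)`).
#' @param early_days early-dropout span in days (default 2).
#' @return list with `per_learner`, `per_arm` tibbles and
#'   `relative_to_random` (percent differences of the return fraction).
#' @export
engagement_metrics <- function(log, return_window = c(4, 7),
                               early_days = 2) {
  stopifnot(inherits(log, "review_log"))
  sessions <- tibble::as_tibble(log) |>
    dplyr::distinct(.data$learner_id, .data$session_id, .data$time,
                    .data$arm)
  per_learner <- sessions |>
    dplyr::group_by(.data$learner_id, .data$arm) |>
    dplyr::summarise(
      first = min(.data$time),
      returned_4_7 = any(.data$time >= min(.data$time) + return_window[1] &
                           .data$time <= min(.data$time) + return_window[2]),
      early_stop = max(.data$time) - min(.data$time) <= early_days,
      .groups = "drop")
  per_arm <- per_learner |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n_learners = dplyr::n(),
                     frac_return_4_7 = mean(.data$returned_4_7),
                     frac_early_stop = mean(.data$early_stop),
                     .groups = "drop")
  rel <- NULL
  if ("random" %in% per_arm$arm) {
    base <- per_arm$frac_return_4_7[per_arm$arm == "random"]
    if (is.finite(base) && base > 0) {
      rel <- setNames(100 * (per_arm$frac_return_4_7 / base - 1),
                      per_arm$arm)
    }
  }
  list(per_learner = per_learner, per_arm = per_arm,
       relative_to_random = rel)
}

#' Minimal box-plot export of the controlled comparison
#'
#' One panel per review stratum, one box per (T bin, arm): quartiles of
#' the normalized empirical forgetting rate with the median marked. Lower
#' is better.
#'
#' @param binned tibble from [bin_by_controls()].
#' @param log_scale plot the rate on a log axis (default TRUE; the rates
#'   are heavily right-skewed).
#' @return a ggplot object.
#' @export
plot_comparison <- function(binned, log_scale = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_comparison requires the ggplot2 package")
  }
  p <- ggplot2::ggplot(binned, ggplot2::aes(
    x = factor(.data$t_bin), y = .data$normalized_rate,
    fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 0) +
    ggplot2::facet_wrap(~n_reviews, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "study period (T) bin",
                  y = "normalized empirical forgetting rate",
                  fill = "arm") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Run the full evaluation of a trial log
#'
#' Chains the evaluation pipeline: per-pair sequence summaries (with the
#' initial-difficulty normalizer estimated from the log itself),
#' controlled binning, per-cell arm comparisons, per-stratum
#' spacing-effect regressions, and engagement metrics.
#'
#' @param log a [review_log()] (already preprocessed).
#' @param n0_map optional named vector of initial-difficulty rates; when
#'   `NULL` it is estimated from the log via [estimate_initial_rates()].
#' @param epsilon smoothing constant (default 0.01).
#' @param n_reviews_range review-count strata (default `2:7`).
#' @param n_t_bins T bins per stratum (default 3).
#' @param alpha_level family significance level (default 0.05).
#' @param n0_method estimator for the normalizer when `n0_map` is `NULL`.
#' @return list with `summaries`, `binned`, `comparison`, `regressions`
#'   (row-bound [fit_eq1()] results over the strata with all arms
#'   present), `engagement`, and the `n0_map` used.
#' @export
evaluate_trial <- function(log, n0_map = NULL, epsilon = 0.01,
                           n_reviews_range = 2:7, n_t_bins = 3,
                           alpha_level = 0.05,
                           n0_method = c("fitted", "empirical")) {
  n0_method <- match.arg(n0_method)
  if (is.null(n0_map)) {
    n0_map <- estimate_initial_rates(log, method = n0_method,
                                     epsilon = epsilon)
  }
  sequences <- build_sequences(log)
  summaries <- summarize_sequences(sequences, n0_map, epsilon)
  binned <- bin_by_controls(summaries, n_reviews_range, n_t_bins)
  comparison <- compare_arms(binned, alpha_level)
  regressions <- dplyr::bind_rows(lapply(
    intersect(n_reviews_range, unique(summaries$n_reviews)),
    function(nr) {
      df <- summaries[summaries$n_reviews == nr, , drop = FALSE]
      if (nrow(df) < 10 || !all(ARM_LEVELS %in% df$arm)) return(NULL)
      fit_eq1(df)
    }))
  list(summaries = summaries, binned = binned, comparison = comparison,
       regressions = regressions, engagement = engagement_metrics(log),
       n0_map = n0_map, epsilon = epsilon)
}
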