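#' Recall probability under the exponential forgetting curve
#'
#' A learner recalls an item with probability `m = exp(-n * delta)`, where
#' `n` is the item's current forgetting rate (1/day) and `delta` the time
#' since its last review (days). Vectorized over both arguments.
#'
#' @param n forgetting rate(s), 1/day, `>= 0`.
#' @param delta time(s) since last review, days, `>= 0`.
#' @return recall probability in `(0, 1]`.
#' @export
#' @examples
#' recall_probability(0.1, 0)            # 1: nothing forgotten yet
#' recall_probability(log(2), 1)         # 0.5 at one half-life
recall_probability <- function(n, delta) {
  if (any(!is.finite(n)) || any(n < 0)) abort("`n` must be finite and >= 0")
  if (any(!is.finite(delta)) || any(delta < 0)) {
    abort("`delta` must be finite and >= 0")
  }
  exp(-n * delta)
}

#' Memory state of one (learner, item) pair
#'
#' @param n current forgetting rate, 1/day, `> 0`.
#' @param last_review_time time of the last review in days, or `NA` if the
#'   item has never been reviewed.
#' @param successes,failures counts of past recalled / forgotten reviews.
#' @return an object of class `memory_state`.
#' @export
memory_state <- function(n, last_review_time = NA_real_, successes = 0L,
                         failures = 0L) {
  assert_scalar_number(n, "n", lower = 0, strict_lower = TRUE)
  stopifnot(successes >= 0, failures >= 0)
  structure(list(n = n, last_review_time = last_review_time,
                 successes = as.integer(successes),
                 failures = as.integer(failures)),
            class = "memory_state")
}

#' Update a memory state after one review
#'
#' The forgetting rate shrinks multiplicatively by `(1 - alpha)` after a
#' successful recall and grows by `(1 + beta)` after a failure; counts are
#' incremented accordingly. The rate stays strictly positive for
#' `alpha < 1`.
#'
#' @param state a [memory_state()].
#' @param recall 0 (forgot) or 1 (recalled).
#' @param params an [hlr_params()] object (only `alpha`, `beta` are used).
#' @param time review time in days, recorded as the new
#'   `last_review_time` (optional).
#' @return the updated [memory_state()].
#' @export
update_forgetting_rate <- function(state, recall, params, time = NA_real_) {
  stopifnot(inherits(state, "memory_state"))
  if (!(is.numeric(recall) && length(recall) == 1L && recall %in% c(0, 1))) {
    abort("`recall` must be 0 or 1")
  }
  n_new <- if (recall == 1) state$n * (1 - params$alpha)
           else state$n * (1 + params$beta)
  memory_state(n_new, last_review_time = time,
               successes = state$successes + (recall == 1),
               failures = state$failures + (recall == 0))
}

#' Parameters of the count-based half-life-regression model
#'
#' The model predicts the forgetting rate of a (learner, item) pair from
#' its review history: `n = n0[item] * (1 - alpha)^successes *
#' (1 + beta)^failures`, with per-item initial rates `n0` (the item's
#' initial difficulty) and global success/failure multipliers.
#'
#' @param n0 named numeric vector of initial forgetting rates (1/day, > 0),
#'   names are item ids.
#' @param alpha success multiplier parameter in `[0, 1)`.
#' @param beta failure multiplier parameter `>= 0`.
#' @param l2 regularization weight used when fitting (kept for provenance).
#' @return an object of class `hlr_params`.
#' @export
hlr_params <- function(n0, alpha, beta, l2 = 0) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(beta, "beta", lower = 0)
  assert_scalar_number(l2, "l2", lower = 0)
  if (length(n0) > 0 && (is.null(names(n0)) || any(!nzchar(names(n0))))) {
    abort("`n0` must be a named vector (names are item ids)")
  }
  if (any(!is.finite(n0)) || any(n0 <= 0)) abort("all `n0` must be > 0")
  structure(list(n0 = n0, alpha = alpha, beta = beta, l2 = l2),
            class = "hlr_params")
}

#' @export
print.hlr_params <- function(x, ...) {
  cat(sprintf("<hlr_params> %d items | alpha = %.4f, beta = %.4f, l2 = %g\n",
              length(x$n0), x$alpha, x$beta, x$l2))
  cat(sprintf("  n0: median %.4f/day [%.4f, %.4f]\n",
              median(x$n0), min(x$n0), max(x$n0)))
  invisible(x)
}

#' Predicted forgetting rate from review counts
#'
#' Closed form of the count-based model: folding
#' [update_forgetting_rate()] over a history with `successes_before`
#' recalls and `failures_before` failures gives
#' `n0 * (1 - alpha)^s * (1 + beta)^f`, independent of order.
#'
#' @param observations a data frame with columns `item_id`,
#'   `successes_before`, `failures_before` (a [recall_observations()]
#'   table works).
#' @param params an [hlr_params()].
#' @return numeric vector of rates (1/day).
#' @export
predicted_rate <- function(observations, params) {
  stopifnot(inherits(params, "hlr_params"))
  unknown <- setdiff(unique(observations$item_id), names(params$n0))
  if (length(unknown) > 0) {
    abort(sprintf("no fitted n0 for item(s): %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "spacedselect_lookup_error")
  }
  params$n0[observations$item_id] *
    (1 - params$alpha)^observations$successes_before *
    (1 + params$beta)^observations$failures_before
}

#' Extract recall observations from a review log
#'
#' One observation per review that has a predecessor for the same
#' (learner, question) pair: the elapsed interval, the counts of previous
#' successes/failures within the pair, and the binary outcome. The first
#' review of a pair has no defined interval and is returned separately
#' (it seeds the initial-rate estimates).
#'
#' @param log a [review_log()].
#' @return a list with `observations` (tibble: `learner_id`, `item_id`,
#'   `delta`, `successes_before`, `failures_before`, `recall`) and
#'   `first_reviews` (tibble: `learner_id`, `item_id`, `time`, `recall`).
#' @export
recall_observations <- function(log) {
  stopifnot(inherits(log, "review_log"))
  events <- tibble::as_tibble(log)
  if (nrow(events) == 0) {
    return(list(
      observations = tibble::tibble(
        learner_id = character(), item_id = character(), delta = double(),
        successes_before = integer(), failures_before = integer(),
        recall = integer()),
      first_reviews = tibble::tibble(
        learner_id = character(), item_id = character(), time = double(),
        recall = integer())))
  }
  events <- events |>
    dplyr::arrange(.data$learner_id, .data$question_id, .data$time) |>
    dplyr::group_by(.data$learner_id, .data$question_id) |>
    dplyr::mutate(
      idx = dplyr::row_number(),
      delta = .data$time - dplyr::lag(.data$time),
      successes_before = cumsum(dplyr::lag(.data$recall, default = 0L)),
      failures_before = cumsum(dplyr::lag(1L - .data$recall, default = 0L))
    ) |>
    dplyr::ungroup()
  list(
    observations = events |>
      dplyr::filter(.data$idx > 1L) |>
      dplyr::transmute(.data$learner_id, item_id = .data$question_id,
                       .data$delta, .data$successes_before,
                       .data$failures_before, .data$recall),
    first_reviews = events |>
      dplyr::filter(.data$idx == 1L) |>
      dplyr::transmute(.data$learner_id, item_id = .data$question_id,
                       .data$time, .data$recall))
}

# ---- fitting ---------------------------------------------------------------

hlr_initial_n0 <- function(observations, items) {
  # method-of-moments per item from each pair's first interval observation:
  # solve mean(recall) = exp(-n0 * median(delta)) with clamped proportions
  first_obs <- observations |>
    dplyr::filter(.data$successes_before + .data$failures_before <= 1L)
  global <- 0.3
  if (nrow(first_obs) > 0) {
    p_all <- min(max(mean(first_obs$recall), 0.05), 0.95)
    global <- -log(p_all) / stats::median(first_obs$delta)
  }
  n0 <- setNames(rep(global, length(items)), items)
  if (nrow(first_obs) > 0) {
    per_item <- first_obs |>
      dplyr::group_by(.data$item_id) |>
      dplyr::summarise(p = min(max(mean(.data$recall), 0.05), 0.95),
                       d = stats::median(.data$delta), .groups = "drop")
    est <- -log(per_item$p) / per_item$d
    est[!is.finite(est) | est <= 0] <- global
    n0[per_item$item_id] <- est
  }
  pmin(pmax(n0, 1e-4), 100)
}

#' Fit the count-based half-life-regression model
#'
#' Minimizes the penalized squared-error risk
#' `sum((recall - exp(-n * delta))^2) + l2 * (sum((log n0 - mu0)^2) +
#' alpha^2 + beta^2)` over per-item `log n0` and the transformed global
#' multipliers, where `n = n0[item] * (1-alpha)^s * (1+beta)^f` and `mu0`
#' is the shared log-rate prior mean taken from the method-of-moments
#' initialization. Optimization is quasi-Newton (BFGS) with analytic
#' gradients in unconstrained transforms (`log n0`, logit `alpha`,
#' `log beta`), so the invariants `n0 > 0`, `alpha` in `[0,1)`,
#' `beta >= 0` hold by construction. Deterministic given the data and
#' initialization.
#'
#' @param observations observation table as produced by
#'   [recall_observations()]`$observations` (columns `item_id`, `delta`,
#'   `successes_before`, `failures_before`, `recall`).
#' @param l2 regularization weight (default `1e-3`).
#' @param init optional [hlr_params()] to start from.
#' @param control list: `maxit` (default 500), `reltol` on the objective
#'   (default 1e-10).
#' @return an [hlr_params()] with attributes `objective` (final penalized
#'   risk) and `convergence` (0 for success).
#' @export
fit_hlr <- function(observations, l2 = 1e-3, init = NULL,
                    control = list()) {
  control <- modifyList(list(maxit = 500L, reltol = 1e-10), control)
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("item_id", "delta", "successes_before", "failures_before",
                  "recall") %in% names(obs)))
  if (nrow(obs) == 0) abort("no observations to fit")
  if (any(obs$delta <= 0)) abort("all observation deltas must be > 0")
  items <- sort(unique(obs$item_id))
  item_idx <- match(obs$item_id, items)

  # weakly identified items: a single distinct delta and all-identical
  # outcomes pin n0 only through the penalty
  flagged <- obs |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(weak = dplyr::n_distinct(round(.data$delta, 9)) == 1L &&
                       dplyr::n_distinct(.data$recall) == 1L,
                     .groups = "drop")
  if (any(flagged$weak)) {
    warn(sprintf("weakly identified item(s): %s",
                 paste(head(flagged$item_id[flagged$weak], 5),
                       collapse = ", ")))
  }

  if (is.null(init)) {
    n0_init <- hlr_initial_n0(obs, items)
    alpha_init <- 0.1
    beta_init <- 0.1
  } else {
    n0_init <- pmin(pmax(init$n0[items], 1e-6), 1e3)
    alpha_init <- min(max(init$alpha, 1e-6), 1 - 1e-6)
    beta_init <- max(init$beta, 1e-6)
  }
  mu0 <- mean(log(n0_init))
  theta0 <- c(log(n0_init), qlogis(alpha_init), log(beta_init))
  n_items <- length(items)
  s <- obs$successes_before
  f <- obs$failures_before
  delta <- obs$delta
  r <- obs$recall

  unpack <- function(theta) {
    list(log_n0 = theta[seq_len(n_items)],
         alpha = plogis(theta[n_items + 1L]),
         beta = exp(theta[n_items + 2L]))
  }
  objective <- function(theta) {
    p <- unpack(theta)
    n <- exp(p$log_n0[item_idx] + s * log1p(-p$alpha) + f * log1p(p$beta))
    m <- exp(-n * delta)
    sum((r - m)^2) +
      l2 * (sum((p$log_n0 - mu0)^2) + p$alpha^2 + p$beta^2)
  }
  gradient <- function(theta) {
    p <- unpack(theta)
    log_n <- p$log_n0[item_idx] + s * log1p(-p$alpha) + f * log1p(p$beta)
    n <- exp(log_n)
    m <- exp(-n * delta)
    # d loss / d n per observation
    dn <- 2 * (r - m) * m * delta
    g_logn0 <- as.numeric(
      tapply(dn * n, factor(item_idx, levels = seq_len(n_items)), sum,
             default = 0))
    g_logn0 <- g_logn0 + 2 * l2 * (p$log_n0 - mu0)
    dalpha <- sum(dn * n * (-s) / (1 - p$alpha)) + 2 * l2 * p$alpha
    dbeta <- sum(dn * n * f / (1 + p$beta)) + 2 * l2 * p$beta
    c(g_logn0,
      dalpha * p$alpha * (1 - p$alpha),   # chain: logit transform
      dbeta * p$beta)                     # chain: log transform
  }
  fit <- optim(theta0, objective, gradient, method = "BFGS",
               control = list(maxit = control$maxit,
                              reltol = control$reltol))
  p <- unpack(fit$par)
  out <- hlr_params(setNames(exp(p$log_n0), items),
                    alpha = min(p$alpha, 1 - 1e-12), beta = p$beta, l2 = l2)
  attr(out, "objective") <- fit$value
  attr(out, "convergence") <- fit$convergence
  attr(out, "initial_objective") <- objective(theta0)
  out
}

#' Estimate per-item initial forgetting rates from a review log
#'
#' The normalizer of the normalized empirical forgetting rate. Two
#' estimators: `"fitted"` (default) fits the half-life-regression model on
#' each pair's first-interval observation only, so per-item `n0` is the
#' model's initial-difficulty rate; `"empirical"` takes the per-item median
#' of the empirical forgetting rate of first intervals.
#'
#' @param log a [review_log()].
#' @param method `"fitted"` or `"empirical"`.
#' @param epsilon recall-probability floor used by the empirical
#'   estimator (see [empirical_forgetting_rate()]).
#' @param l2 penalty weight for the fitted estimator.
#' @return named numeric vector of rates (1/day) for every item appearing
#'   in the log; items never observed with a first interval get the global
#'   median (cold start).
#' @export
estimate_initial_rates <- function(log, method = c("fitted", "empirical"),
                                   epsilon = 0.01, l2 = 1e-3) {
  method <- match.arg(method)
  all_items <- sort(unique(log$question_id))
  obs <- recall_observations(log)$observations |>
    dplyr::filter(.data$successes_before + .data$failures_before <= 1L)
  if (nrow(obs) == 0) {
    abort("log has no pair with a second review; cannot estimate n0")
  }
  n0 <- if (method == "fitted") {
    fit_hlr(obs, l2 = l2)$n0
  } else {
    rates <- empirical_forgetting_rate(obs$delta, obs$recall, epsilon)
    out <- tapply(rates, obs$item_id, median)
    setNames(as.numeric(out), names(out))
  }
  # cold start: items never seen with a measurable interval
  missing_items <- setdiff(all_items, names(n0))
  if (length(missing_items) > 0) {
    n0 <- c(n0, setNames(rep(median(n0), length(missing_items)),
                         missing_items))
  }
  n0[sort(names(n0))]
}

#' Serialize / deserialize fitted model parameters as JSON
#'
#' @param params an [hlr_params()].
#' @param path file path.
#' @return `read_hlr_params` returns an [hlr_params()];
#'   `write_hlr_params` returns `path` invisibly.
#' @export
write_hlr_params <- function(params, path) {
  stopifnot(inherits(params, "hlr_params"))
  jsonlite::write_json(
    list(alpha = params$alpha, beta = params$beta, l2 = params$l2,
         n0 = as.list(params$n0)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hlr_params
#' @export
read_hlr_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  hlr_params(unlist(obj$n0), alpha = obj$alpha, beta = obj$beta,
             l2 = obj$l2)
}
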