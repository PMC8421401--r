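#' Configuration of a synthetic learner population
#'
#' Defines the in-silico randomized trial: a population of learners, each
#' randomized once to an arm, initiating study sessions as a homogeneous
#' Poisson process until the horizon or permanent dropout, with session
#' sizes drawn from a shifted geometric distribution and recall outcomes
#' generated by the exponential forgetting-curve model with multiplicative
#' rate dynamics.
#'
#' @param n_learners number of learners (default 1500).
#' @param n_items number of questions in the bank (default 100).
#' @param arm_probabilities length-3 probability vector for assignment to
#'   the select / difficulty / random arms (must sum to 1).
#' @param n0_median,n0_sigma log-normal initial-difficulty distribution:
#'   `n0 ~ exp(Normal(log(n0_median), n0_sigma))`, in 1/day. The defaults
#'   (median 0.04/day — an initial half-life of about 17 days, as expected
#'   for easy declarative multiple-choice content — with sigma 1) span
#'   initial half-lives from a few days to about seven weeks and, at the
#'   default review density, keep the simulated overall recall rate in
#'   the 60-80% band observed in deployed spaced-repetition systems.
#' @param true_alpha,true_beta ground-truth success/failure multipliers
#'   (defaults 0.3 and 0.6).
#' @param session_rate session-arrival intensity, sessions/day per learner
#'   (default 0.5: a study session every other day on average, which with
#'   the default session size reproduces the per-pair review density of
#'   large driving-school trial datasets, about 3 reviews per touched
#'   (learner, question) pair over the horizon).
#' @param session_size_mean mean session size; sizes are
#'   `1 + Geometric(1/mean)` so every session has at least one item
#'   (default 10).
#' @param horizon_days trial length in days (default 60).
#' @param dropout_hazard per-day probability of permanently leaving
#'   (default 0.01; 0 disables dropout).
#' @param q SELECT trade-off parameter (default 1).
#' @param delta0_ref reference delay (days) against which the outcome of a
#'   first-ever exposure is drawn: `Bernoulli(exp(-n0 * delta0_ref))`,
#'   modelling prior familiarity with the material (default 1).
#' @param first_exposure `"reference-delay"` (default) or
#'   `"always-incorrect"`.
#' @param scheduler `"oracle"` (select arm schedules with the true
#'   parameters, isolating policy value from estimation error; default) or
#'   `"estimated"` (refits the model on accumulated data every
#'   `refit_every` sessions per learner, initial rates from the prior
#'   median).
#' @param refit_every refit period, in sessions per learner, for the
#'   estimated scheduler (default 10).
#' @param policy_override `NULL` (default: each arm runs its own policy)
#'   or one of `"select"`, `"difficulty"`, `"random"`: every learner is
#'   scheduled by that single policy while keeping their assigned arm
#'   label. This creates a null trial in which arm labels carry no signal,
#'   used to calibrate the evaluation statistics.
#' @param seed root seed; all randomness fans out from it through named
#'   substreams.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_learners = 1500, n_items = 100,
                              arm_probabilities = c(select = 1/3,
                                                    difficulty = 1/3,
                                                    random = 1/3),
                              n0_median = 0.04, n0_sigma = 1,
                              true_alpha = 0.3, true_beta = 0.6,
                              session_rate = 0.5, session_size_mean = 10,
                              horizon_days = 60, dropout_hazard = 0.01,
                              q = 1, delta0_ref = 1,
                              first_exposure = c("reference-delay",
                                                 "always-incorrect"),
                              scheduler = c("oracle", "estimated"),
                              refit_every = 10L, policy_override = NULL,
                              seed = 1L) {
  first_exposure <- match.arg(first_exposure)
  scheduler <- match.arg(scheduler)
  if (!is.null(policy_override) &&
      !(is.character(policy_override) && length(policy_override) == 1L &&
        policy_override %in% ARM_LEVELS)) {
    abort("policy_override must be NULL or one of 'select', 'difficulty', 'random'",
          class = "spacedselect_config_error")
  }
  problems <- character()
  check <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  check(is.numeric(n_learners) && n_learners >= 1, "n_learners must be >= 1")
  check(is.numeric(n_items) && n_items >= 1, "n_items must be >= 1")
  check(is.numeric(arm_probabilities) && length(arm_probabilities) == 3 &&
          all(arm_probabilities >= 0) &&
          abs(sum(arm_probabilities) - 1) < 1e-12,
        "arm_probabilities must be 3 non-negative values summing to 1")
  check(is.numeric(n0_median) && n0_median > 0, "n0_median must be > 0")
  check(is.numeric(n0_sigma) && n0_sigma >= 0, "n0_sigma must be >= 0")
  check(is.numeric(true_alpha) && true_alpha >= 0 && true_alpha < 1,
        "true_alpha must be in [0, 1)")
  check(is.numeric(true_beta) && true_beta >= 0, "true_beta must be >= 0")
  check(is.numeric(session_rate) && session_rate >= 0,
        "session_rate must be >= 0")
  check(is.numeric(session_size_mean) && session_size_mean >= 1,
        "session_size_mean must be >= 1")
  check(is.numeric(horizon_days) && horizon_days > 0,
        "horizon_days must be > 0")
  check(is.numeric(dropout_hazard) && dropout_hazard >= 0 &&
          dropout_hazard < 1, "dropout_hazard must be in [0, 1)")
  check(is.numeric(q) && q >= 1, "q must be >= 1")
  check(is.numeric(delta0_ref) && delta0_ref > 0, "delta0_ref must be > 0")
  if (length(problems) > 0) {
    abort(paste0("invalid population config:\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "spacedselect_config_error")
  }
  structure(list(
    n_learners = as.integer(n_learners), n_items = as.integer(n_items),
    arm_probabilities = setNames(as.numeric(arm_probabilities), ARM_LEVELS),
    n0_median = n0_median, n0_sigma = n0_sigma,
    true_alpha = true_alpha, true_beta = true_beta,
    session_rate = session_rate, session_size_mean = session_size_mean,
    horizon_days = horizon_days, dropout_hazard = dropout_hazard,
    q = q, delta0_ref = delta0_ref, first_exposure = first_exposure,
    scheduler = scheduler, refit_every = as.integer(refit_every),
    policy_override = policy_override,
    seed = as.integer(seed)), class = "population_config")
}

#' Randomize learners to trial arms
#'
#' Independent categorical assignment, fixed per learner for the whole
#' horizon, reproducible from the seed.
#'
#' @param n_learners number of learners.
#' @param probabilities length-3 probability vector over
#'   select/difficulty/random.
#' @param seed integer seed.
#' @return character vector of arm labels, length `n_learners`.
#' @export
assign_arms <- function(n_learners, probabilities, seed = 1L) {
  if (!(is.numeric(probabilities) && length(probabilities) == 3 &&
        all(probabilities >= 0) && abs(sum(probabilities) - 1) < 1e-12)) {
    abort("`probabilities` must be 3 non-negative values summing to 1")
  }
  withr::with_seed(substream_seed(seed, "assignment"),
                   sample(ARM_LEVELS, n_learners, replace = TRUE,
                          prob = probabilities))
}

learner_ids <- function(n) sprintf("L%05d", seq_len(n))
item_ids <- function(n) sprintf("Q%04d", seq_len(n))

#' Simulate an in-silico randomized controlled trial
#'
#' For each learner: one arm assignment; session times from a homogeneous
#' Poisson process truncated at the horizon or at a geometric dropout
#' time; at each session the items are chosen by the learner's arm policy
#' and each reviewed item's recall is drawn from the exponential
#' forgetting curve at its current true rate, after which the true rate is
#' updated by the multiplicative rule. The select arm schedules with the
#' true parameters by default ("oracle" mode), so the comparison isolates
#' the value of the selection policy from estimation error.
#'
#' @param config a [population_config()].
#' @return a list with `log` (a [review_log()]) and `truth` (class
#'   `ground_truth`): per-item true `n0`, `alpha`, `beta`, per-learner
#'   `arms`, and `trajectory`, a tibble aligned row-for-row with the log
#'   carrying the latent rate `n_before`, the interval `delta` and the
#'   recall probability `m` used for each draw.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "population_config"))
  items <- item_ids(config$n_items)
  learners <- learner_ids(config$n_learners)
  n0_true <- withr::with_seed(
    substream_seed(config$seed, "item-difficulty"),
    setNames(exp(log(config$n0_median) +
                   config$n0_sigma * stats::rnorm(config$n_items)), items))
  arms <- setNames(assign_arms(config$n_learners, config$arm_probabilities,
                               config$seed), learners)
  params_true <- hlr_params(n0_true, config$true_alpha, config$true_beta)

  configs <- lapply(setNames(ARM_LEVELS, ARM_LEVELS), function(a) {
    policy_config(arm = a, items = items, n0 = n0_true, q = config$q,
                  seed = substream_seed(config$seed, "policy"))
  })

  sched_params <- params_true          # oracle mode
  if (config$scheduler == "estimated") {
    prior_n0 <- setNames(rep(config$n0_median, config$n_items), items)
    sched_params <- hlr_params(prior_n0, 0.1, 0.1)
  }
  est_obs <- vector("list", 0)          # accumulated data (estimated mode)

  per_learner <- vector("list", config$n_learners)
  traj <- vector("list", config$n_learners)
  p_size <- 1 / config$session_size_mean

  for (li in seq_len(config$n_learners)) {
    lid <- learners[li]
    label <- arms[[lid]]
    arm <- if (is.null(config$policy_override)) label
           else config$policy_override
    pc <- configs[[arm]]
    lseed <- substream_seed(config$seed, paste0("learner:", lid))
    res <- withr::with_seed(lseed, {
      eff_horizon <- config$horizon_days
      if (config$dropout_hazard > 0) {
        eff_horizon <- min(eff_horizon, rgeom(1, config$dropout_hazard) + 1)
      }
      n_sessions <- rpois(1, config$session_rate * eff_horizon)
      times <- sort(runif(n_sessions, 0, eff_horizon))
      sizes <- if (n_sessions > 0) 1L + rgeom(n_sessions, p_size) else integer()

      n_cur <- unname(n0_true)                       # latent true rates
      n_sched <- unname(sched_params$n0[items])      # scheduler's estimates
      last_t <- rep(NA_real_, config$n_items)
      pointer <- 0L
      names(n_cur) <- names(n_sched) <- names(last_t) <- items

      # grow-by-chunk accumulators; one tibble per learner, not per session
      cap <- max(16L, sum(sizes))
      acc_item <- integer(cap); acc_sess <- integer(cap)
      acc_time <- double(cap); acc_recall <- integer(cap)
      acc_nbef <- double(cap); acc_delta <- double(cap)
      acc_first <- logical(cap); acc_m <- double(cap)
      used <- 0L
      for (si in seq_len(n_sessions)) {
        t_now <- times[[si]]
        k <- sizes[[si]]
        if (arm == "select") {
          seen <- !is.na(last_t)
          unseen_items <- pc$difficulty_order[
            !seen[match(pc$difficulty_order, items)]]
          seen_items <- items[seen]
          if (length(seen_items) > 0) {
            m_seen <- exp(-n_sched[seen_items] *
                            pmax(t_now - last_t[seen_items], 0))
            p_star <- (1 - m_seen) / sqrt(config$q)
            seen_items <- seen_items[order(-p_star, seen_items,
                                           method = "radix")]
          }
          session <- head(c(unseen_items, seen_items), k)
        } else if (arm == "difficulty") {
          idx <- (pointer + seq_len(k) - 1L) %% config$n_items
          pointer <- as.integer((pointer + k) %% config$n_items)
          session <- pc$difficulty_order[idx + 1L]
        } else {
          session <- sample(items, k, replace = TRUE)
        }
        session <- unique(session)     # one outcome per item per sitting
        ii <- match(session, items)
        first <- is.na(last_t[ii])
        delta <- ifelse(first, config$delta0_ref, t_now - last_t[ii])
        n_before <- n_cur[ii]
        m <- ifelse(first,
                    if (config$first_exposure == "always-incorrect") 0
                    else exp(-n0_true[ii] * config$delta0_ref),
                    exp(-n_before * delta))
        recall <- as.integer(runif(length(session)) < m)
        mult <- ifelse(recall == 1, 1 - config$true_alpha,
                       1 + config$true_beta)
        n_cur[ii] <- n_before * mult
        n_sched[ii] <- n_sched[ii] * ifelse(
          recall == 1, 1 - sched_params$alpha, 1 + sched_params$beta)
        last_t[ii] <- t_now
        span <- used + seq_along(ii)
        acc_item[span] <- ii
        acc_sess[span] <- si
        acc_time[span] <- t_now
        acc_recall[span] <- recall
        acc_nbef[span] <- unname(n_before)
        acc_delta[span] <- unname(delta)
        acc_first[span] <- first
        acc_m[span] <- unname(m)
        used <- used + length(ii)
      }
      span <- seq_len(used)
      list(
        ev = tibble::tibble(
          learner_id = lid, question_id = items[acc_item[span]],
          session_id = sprintf("%s-s%04d", lid, acc_sess[span]),
          time = acc_time[span], recall = acc_recall[span], arm = label),
        tr = tibble::tibble(
          learner_id = lid, question_id = items[acc_item[span]],
          time = acc_time[span], n_before = acc_nbef[span],
          delta = acc_delta[span], first_exposure = acc_first[span],
          m = acc_m[span]))
    })
    per_learner[[li]] <- res$ev
    traj[[li]] <- res$tr

    if (config$scheduler == "estimated" &&
        li %% max(1L, config$refit_every) == 0L) {
      est_obs[[length(est_obs) + 1L]] <- res$ev
      acc <- dplyr::bind_rows(est_obs)
      if (nrow(acc) > 0) {
        obs <- recall_observations(review_log(acc))$observations
        if (nrow(obs) >= 50) {
          sched_params <- tryCatch(
            fit_hlr(obs, l2 = 1e-3, init = sched_params),
            error = function(e) sched_params)
          miss <- setdiff(items, names(sched_params$n0))
          if (length(miss) > 0) {
            sched_params$n0 <- c(
              sched_params$n0,
              setNames(rep(median(sched_params$n0), length(miss)), miss))
          }
        }
      }
    } else if (config$scheduler == "estimated") {
      est_obs[[length(est_obs) + 1L]] <- res$ev
    }
  }

  events <- dplyr::bind_rows(per_learner)
  log <- review_log(events, metadata = list(
    generator = "simulate_trial", seed = config$seed,
    scheduler = config$scheduler))
  trajectory <- dplyr::bind_rows(traj)
  # align with the log's canonical sort
  ord <- order(trajectory$learner_id, trajectory$time,
               trajectory$question_id, method = "radix")
  truth <- structure(list(
    n0 = n0_true, alpha = config$true_alpha, beta = config$true_beta,
    arms = arms, trajectory = trajectory[ord, , drop = FALSE],
    config = config), class = "ground_truth")
  list(log = log, truth = truth)
}

#' Verify a simulated log against its ground truth
#'
#' Replays the multiplicative rate dynamics over the log and confirms that
#' every latent rate, interval and recall probability used during
#' generation matches the stored trajectory exactly. Guards the simulator
#' and the truth record against drifting apart.
#'
#' @param log a [review_log()] from [simulate_trial()].
#' @param truth the matching `ground_truth`.
#' @param tol numeric comparison tolerance (default 1e-9).
#' @return invisibly `TRUE`; aborts with the first divergent event
#'   otherwise.
#' @export
replay_log <- function(log, truth, tol = 1e-9) {
  stopifnot(inherits(log, "review_log"))
  events <- tibble::as_tibble(log)
  tr <- truth$trajectory
  if (nrow(events) != nrow(tr)) {
    abort(sprintf("log has %d events but trajectory has %d rows",
                  nrow(events), nrow(tr)),
          class = "spacedselect_integrity_error")
  }
  if (nrow(events) == 0) return(invisible(TRUE))
  if (!all(events$learner_id == tr$learner_id) ||
      !all(events$question_id == tr$question_id)) {
    abort("log and trajectory rows are not aligned",
          class = "spacedselect_integrity_error")
  }
  cfg <- truth$config
  state <- new.env(parent = emptyenv())
  fail_at <- function(i, what) {
    abort(sprintf(
      "replay mismatch at event %d (%s, %s, t=%.6f): %s", i,
      events$learner_id[i], events$question_id[i], events$time[i], what),
      class = "spacedselect_integrity_error")
  }
  for (i in seq_len(nrow(events))) {
    key <- paste(events$learner_id[i], events$question_id[i], sep = "\r")
    prev <- state[[key]]
    if (is.null(prev)) {
      n_before <- truth$n0[[events$question_id[i]]]
      delta <- cfg$delta0_ref
      m <- if (cfg$first_exposure == "always-incorrect") 0
           else exp(-n_before * delta)
      if (!isTRUE(tr$first_exposure[i])) fail_at(i, "expected first exposure")
    } else {
      n_before <- prev$n
      delta <- events$time[i] - prev$t
      m <- exp(-n_before * delta)
      if (isTRUE(tr$first_exposure[i])) fail_at(i, "unexpected first exposure")
    }
    if (abs(n_before - tr$n_before[i]) > tol) {
      fail_at(i, sprintf("rate %.9f != recorded %.9f", n_before,
                         tr$n_before[i]))
    }
    if (abs(m - tr$m[i]) > tol) {
      fail_at(i, sprintf("recall probability %.9f != recorded %.9f", m,
                         tr$m[i]))
    }
    mult <- if (events$recall[i] == 1) 1 - truth$alpha else 1 + truth$beta
    state[[key]] <- list(n = n_before * mult, t = events$time[i])
  }
  invisible(TRUE)
}

#' Serialize a ground-truth record to JSON
#'
#' The full latent trajectory is omitted by default (it is as large as the
#' log); arm assignments and the generative parameters are always kept.
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @param include_trajectory write the per-event latent states too?
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(truth, path, include_trajectory = FALSE) {
  obj <- list(alpha = truth$alpha, beta = truth$beta,
              n0 = as.list(truth$n0), arms = as.list(truth$arms))
  if (include_trajectory) obj$trajectory <- truth$trajectory
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
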