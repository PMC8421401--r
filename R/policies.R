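#' Optimal selection probability of the SELECT policy
#'
#' The closed-form solution of the session-construction control problem:
#' an item currently recalled with probability `m` is included in the next
#' study session with probability `p* = (1 - m) / sqrt(q)`. The parameter
#' `q >= 1` trades off recall probability upon review against session
#' size: larger `q` means shorter sessions. Perfectly remembered items
#' (`m = 1`) are never selected. Vectorized over `m`.
#'
#' @param m recall probability/probabilities in `[0, 1]`.
#' @param q trade-off parameter, `>= 1` (default 1; rankings are agnostic
#'   to `q` since it rescales all probabilities equally).
#' @return selection probability/probabilities in `[0, 1/sqrt(q)]`.
#' @export
#' @examples
#' select_probability(c(0, 0.5, 1), q = 4)   # 0.50 0.25 0.00
select_probability <- function(m, q = 1) {
  assert_scalar_number(q, "q", lower = 1)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort("`m` must be in [0, 1]")
  }
  pmin(pmax((1 - m) / sqrt(q), 0), 1)
}

#' Policy configuration for one trial arm
#'
#' @param arm `"select"`, `"difficulty"` or `"random"`.
#' @param items character vector: the item universe.
#' @param n0 named numeric vector of initial-difficulty rates (1/day) used
#'   to order items easiest-first; required for the select and difficulty
#'   arms.
#' @param q SELECT trade-off parameter (`>= 1`, default 1).
#' @param seed integer seed for the random arm's per-learner streams.
#' @param sample_sessions if `TRUE` the select arm draws Bernoulli(`p*`)
#'   inclusions instead of deterministic ranking (the deployed app ranks).
#' @return an object of class `policy_config`. `difficulty_order` is the
#'   item universe sorted ascending by `n0` (easier first), ties broken by
#'   item id.
#' @export
policy_config <- function(arm = c("select", "difficulty", "random"),
                          items, n0 = NULL, q = 1, seed = 1L,
                          sample_sessions = FALSE) {
  arm <- match.arg(arm)
  assert_scalar_number(q, "q", lower = 1)
  items <- as.character(items)
  if (length(items) == 0) abort("item universe must be nonempty")
  if (arm %in% c("select", "difficulty")) {
    if (is.null(n0)) abort(sprintf("arm '%s' requires `n0`", arm))
    missing_n0 <- setdiff(items, names(n0))
    if (length(missing_n0) > 0) {
      abort(sprintf("`n0` missing for item(s): %s",
                    paste(head(missing_n0, 5), collapse = ", ")))
    }
    difficulty_order <- items[order(n0[items], items, method = "radix")]
  } else {
    difficulty_order <- sort(items)
  }
  structure(list(arm = arm, items = sort(items), n0 = n0, q = q,
                 seed = as.integer(seed), sample_sessions = sample_sessions,
                 difficulty_order = difficulty_order),
            class = "policy_config")
}

#' Per-learner scheduler state
#'
#' Persistent state between a learner's sessions: current per-item
#' forgetting-rate estimates and last-review times (select arm), the
#' circular pointer (difficulty arm), and a private RNG stream seeded from
#' (policy seed, learner id) so learners are independent and reproducible.
#'
#' @param config a [policy_config()].
#' @param learner_id learner identifier (seeds the RNG stream).
#' @return an object of class `scheduler_state` with fields `n` (named
#'   rate vector, initialized at `n0` where available), `last_time` (named,
#'   `NA` = unseen), `pointer` (0-based circular index), `rng_seed`.
#' @export
scheduler_state <- function(config, learner_id = "learner") {
  stopifnot(inherits(config, "policy_config"))
  items <- config$items
  n <- if (!is.null(config$n0)) {
    unname(config$n0[items])
  } else rep(NA_real_, length(items))
  structure(list(
    n = setNames(n, items),
    last_time = setNames(rep(NA_real_, length(items)), items),
    pointer = 0L,
    rng_seed = substream_seed(config$seed, paste0("policy:", learner_id))),
    class = "scheduler_state")
}

#' Record a review in a scheduler state
#'
#' Updates the item's tracked forgetting rate with the multiplicative
#' rule and stamps its last-review time.
#'
#' @param state a [scheduler_state()].
#' @param item item id.
#' @param time review time, days.
#' @param recall 0/1 outcome.
#' @param params an [hlr_params()] supplying `alpha`, `beta`.
#' @return the updated state.
#' @export
observe_review <- function(state, item, time, recall, params) {
  stopifnot(inherits(state, "scheduler_state"))
  state$n[[item]] <- if (recall == 1) state$n[[item]] * (1 - params$alpha)
                     else state$n[[item]] * (1 + params$beta)
  state$last_time[[item]] <- time
  state
}

#' Rank items for a SELECT-arm session
#'
#' Items the learner has never reviewed come first, easiest first
#' (ascending initial difficulty `n0`); already-seen items follow in
#' descending selection probability `p* = (1 - m)/sqrt(q)` evaluated at
#' the current time. Ties are broken by ascending item id, so the ranking
#' is deterministic.
#'
#' @param state a [scheduler_state()] with current rates and last-review
#'   times.
#' @param now current time, days.
#' @param config a [policy_config()] with `arm = "select"`.
#' @return character vector: all items in presentation order.
#' @export
rank_items_select <- function(state, now, config) {
  stopifnot(inherits(state, "scheduler_state"),
            inherits(config, "policy_config"))
  seen <- !is.na(state$last_time)
  unseen_items <- config$difficulty_order[
    config$difficulty_order %in% names(state$last_time)[!seen]]
  seen_items <- names(state$last_time)[seen]
  if (length(seen_items) > 0) {
    delta <- pmax(now - state$last_time[seen_items], 0)
    m <- recall_probability(state$n[seen_items], delta)
    p <- select_probability(m, config$q)
    seen_items <- seen_items[order(-p, seen_items, method = "radix")]
  }
  c(unseen_items, seen_items)
}

#' Next items under the difficulty-ordered circular policy
#'
#' Items are presented in a fixed cycle over the universe sorted easiest
#' first (ascending initial difficulty); the circular pointer persists
#' across sessions, so over `c` full cycles every item is shown exactly
#' `c` times.
#'
#' @param state a [scheduler_state()].
#' @param k number of items, `>= 1`.
#' @param config a [policy_config()] with `arm = "difficulty"`.
#' @return list with `items` (character vector, length `k`) and `state`
#'   (pointer advanced by `k` modulo the universe size).
#' @export
next_items_difficulty <- function(state, k, config) {
  stopifnot(inherits(state, "scheduler_state"), k >= 1)
  m <- length(config$difficulty_order)
  idx <- (state$pointer + seq_len(k) - 1L) %% m
  state$pointer <- as.integer((state$pointer + k) %% m)
  list(items = config$difficulty_order[idx + 1L], state = state)
}

#' Next items under the uniform-random policy
#'
#' `k` independent uniform draws over the item universe, with replacement,
#' from the learner's private seeded RNG stream — reproducible given the
#' policy seed and learner id, and independent of any other randomness.
#'
#' @param state a [scheduler_state()].
#' @param k number of draws, `>= 1`.
#' @param config a [policy_config()] with `arm = "random"`.
#' @return list with `items` (length `k`, may contain duplicates) and
#'   `state` (advanced RNG stream).
#' @export
next_items_random <- function(state, k, config) {
  stopifnot(inherits(state, "scheduler_state"), k >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  if (length(state$rng_seed) == 1L) {
    set.seed(state$rng_seed)   # first draw of this stream
  } else {
    assign(".Random.seed", state$rng_seed, envir = globalenv())
  }
  items <- sample(config$items, k, replace = TRUE)
  state$rng_seed <- get(".Random.seed", globalenv())
  list(items = items, state = state)
}

#' Cut a policy's presentation order into a study session
#'
#' The session set `S` is the first `session_size` items of the policy's
#' order (select/difficulty, no duplicates; truncated to the universe
#' size) or the policy's draw as-is (random, with-replacement semantics).
#'
#' @param ordered_items character vector from [rank_items_select()],
#'   [next_items_difficulty()] or [next_items_random()].
#' @param session_size number of items the learner chose to study,
#'   `>= 1`.
#' @return character vector of at most `session_size` items.
#' @export
build_session <- function(ordered_items, session_size) {
  if (!(is.numeric(session_size) && length(session_size) == 1L &&
        session_size >= 1)) {
    abort("`session_size` must be >= 1")
  }
  head(ordered_items, session_size)
}
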