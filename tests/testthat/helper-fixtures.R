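# Small in-code fixtures shared across the test files.

make_events <- function(learner_id, question_id, time, recall,
                        arm = "random", session_id = NULL) {
  n <- max(length(learner_id), length(question_id), length(time),
           length(recall))
  if (is.null(session_id)) {
    session_id <- paste(rep_len(learner_id, n), rep_len(time, n), sep = "@")
  }
  tibble::tibble(
    learner_id = rep_len(learner_id, n),
    question_id = rep_len(question_id, n),
    session_id = rep_len(session_id, n),
    time = rep_len(time, n),
    recall = as.integer(rep_len(recall, n)),
    arm = rep_len(arm, n))
}

# event columns only, provenance metadata stripped, for equality checks
events_of <- function(log) {
  out <- tibble::as_tibble(log)
  attr(out, "metadata") <- NULL
  out
}

# a 2-learner, 2-arm log with known structure
toy_log <- function() {
  review_log(dplyr::bind_rows(
    make_events("alice", c("q1", "q2"), 0, c(1, 0), arm = "select"),
    make_events("alice", c("q1", "q2"), 3, c(1, 1), arm = "select"),
    make_events("alice", c("q1", "q2"), 10, c(0, 1), arm = "select"),
    make_events("bob", c("q1", "q2"), 0.5, c(0, 0), arm = "random"),
    make_events("bob", c("q1", "q2"), 4, c(1, 0), arm = "random")))
}

# brute-force Huber objective and its gradient, used as the
# generic-optimizer oracle
huber_objective <- function(beta, X, y, k, scale) {
  r <- (y - drop(X %*% beta)) / scale
  sum(ifelse(abs(r) <= k, r^2 / 2, k * abs(r) - k^2 / 2))
}

huber_gradient <- function(beta, X, y, k, scale) {
  r <- (y - drop(X %*% beta)) / scale
  psi <- ifelse(abs(r) <= k, r, k * sign(r))
  -drop(crossprod(X, psi)) / scale
}

# exhaustive-permutation two-sided Mann-Whitney p-value (independent oracle)
mw_enumerate <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  mu <- nx * length(y) / 2
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  us <- apply(splits, 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
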