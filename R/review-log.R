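#' Review logs: the atomic observation stream of a spaced-repetition trial
#'
#' A review log holds one row per (learner, question, session) review event:
#' who answered what, when, correctly or not, and under which trial arm.
#' Times are stored internally in days (floating point); the on-disk
#' canonical formats use epoch seconds, converted once at read.
#'
#' @param events a data frame with columns `learner_id`, `question_id`,
#'   `session_id` (character), `time` (days, numeric), `recall` (0/1 integer)
#'   and `arm` (one of `"select"`, `"difficulty"`, `"random"`, or
#'   `"unknown"`).
#' @param metadata named list of free-form provenance.
#' @return an object of class `review_log`: a tibble of events sorted by
#'   (learner_id, time, question_id), with a `metadata` attribute.
#' @export
#' @examples
#' log <- review_log(tibble::tibble(
#'   learner_id = "u1", question_id = c("q2", "q1"), session_id = "s1",
#'   time = 0, recall = c(1L, 0L), arm = "random"
#' ))
#' nrow(log)
review_log <- function(events, metadata = list()) {
  events <- tibble::as_tibble(events)
  validate_review_events(events)
  events$recall <- as.integer(events$recall)
  events$time <- as.double(events$time)
  # stable sort; ties at (learner, time) broken by question_id for
  # deterministic pipelines
  ord <- order(events$learner_id, events$time, events$question_id,
               method = "radix")
  events <- events[ord, , drop = FALSE]
  structure(events, metadata = metadata,
            class = c("review_log", class(tibble::tibble())))
}

REVIEW_LOG_COLUMNS <- c("learner_id", "question_id", "session_id",
                        "time", "recall", "arm")

validate_review_events <- function(events) {
  missing_cols <- setdiff(REVIEW_LOG_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("review log is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "spacedselect_schema_error")
  }
  if (nrow(events) == 0) return(invisible(events))
  bad_recall <- which(!(events$recall %in% c(0, 1)))
  if (length(bad_recall) > 0) {
    abort(sprintf("`recall` must be 0 or 1; offending row(s): %s",
                  paste(head(bad_recall, 5), collapse = ", ")),
          class = "spacedselect_validation_error")
  }
  bad_time <- which(!is.finite(events$time) | events$time < 0)
  if (length(bad_time) > 0) {
    abort(sprintf("`time` must be finite and non-negative; offending row(s): %s",
                  paste(head(bad_time, 5), collapse = ", ")),
          class = "spacedselect_validation_error")
  }
  bad_arm <- which(!(events$arm %in% c(ARM_LEVELS, "unknown")))
  if (length(bad_arm) > 0) {
    abort(sprintf("`arm` must be one of %s or 'unknown'; offending row(s): %s",
                  paste(sQuote(ARM_LEVELS), collapse = ", "),
                  paste(head(bad_arm, 5), collapse = ", ")),
          class = "spacedselect_validation_error")
  }
  # a session is one sitting of one learner at one time
  by_session <- split(seq_len(nrow(events)), events$session_id)
  for (idx in by_session) {
    if (length(unique(events$learner_id[idx])) > 1L ||
        length(unique(events$time[idx])) > 1L) {
      abort(sprintf(
        "events sharing session_id '%s' must share learner_id and time",
        events$session_id[idx[1]]), class = "spacedselect_validation_error")
    }
  }
  invisible(events)
}

#' @export
print.review_log <- function(x, ...) {
  cat(sprintf("<review_log> %d events, %d learners, %d questions\n",
              nrow(x), length(unique(x$learner_id)),
              length(unique(x$question_id))))
  NextMethod()
}

#' Read a review log from its canonical CSV or JSONL format
#'
#' The canonical CSV header is
#' `learner_id,question_id,session_id,time,recall,arm` (UTF-8, RFC 4180
#' quoting); JSONL carries one event object per line with the same keys.
#' On-disk `time` is in epoch seconds and is converted to days.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; the default guesses from the file
#'   extension.
#' @return a [review_log()].
#' @export
read_review_log <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  if (format == "csv") {
    events <- utils::read.csv(path, colClasses = "character",
                              encoding = "UTF-8")
    missing_cols <- setdiff(REVIEW_LOG_COLUMNS, names(events))
    if (length(missing_cols) > 0) {
      abort(sprintf("%s: missing column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            class = "spacedselect_schema_error")
    }
    events <- tibble::as_tibble(events)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      events <- tibble::as_tibble(
        setNames(rep(list(character()), 6), REVIEW_LOG_COLUMNS))
    } else {
      rows <- lapply(seq_along(lines), function(i) {
        obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                        error = function(e) {
                          abort(sprintf("%s: malformed JSON on line %d", path, i),
                                class = "spacedselect_schema_error")
                        })
        missing_cols <- setdiff(REVIEW_LOG_COLUMNS, names(obj))
        if (length(missing_cols) > 0) {
          abort(sprintf("%s: line %d missing key(s): %s", path, i,
                        paste(missing_cols, collapse = ", ")),
                class = "spacedselect_schema_error")
        }
        tibble::as_tibble(lapply(obj[REVIEW_LOG_COLUMNS], as.character))
      })
      events <- dplyr::bind_rows(rows)
    }
  }
  n <- nrow(events)
  recall_num <- suppressWarnings(as.numeric(events$recall))
  bad <- which(is.na(recall_num) | !(recall_num %in% c(0, 1)))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-binary recall value in data row(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "spacedselect_validation_error")
  }
  time_num <- suppressWarnings(as.numeric(events$time))
  bad <- which(is.na(time_num) | !is.finite(time_num) | time_num < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid time value in data row(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "spacedselect_validation_error")
  }
  events$recall <- as.integer(recall_num)
  events$time <- time_num / SECONDS_PER_DAY
  review_log(events, metadata = list(source = path, format = format))
}

#' Write a review log to its canonical CSV or JSONL format
#'
#' Internal day-valued times are written as epoch seconds. Writing then
#' reading a log is the identity (up to floating-point unit conversion,
#' below 1 part in 1e12).
#'
#' @param log a [review_log()].
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`; default guesses from extension.
#' @return `path`, invisibly.
#' @export
write_review_log <- function(log, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  stopifnot(inherits(log, "review_log"))
  out <- tibble::as_tibble(log)[REVIEW_LOG_COLUMNS]
  out$time <- format(out$time * SECONDS_PER_DAY, digits = 17,
                     scientific = FALSE, trim = TRUE)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(out) > 0) {
      for (i in seq_len(nrow(out))) {
        row <- as.list(out[i, ])
        row$time <- as.numeric(row$time)
        row$recall <- as.integer(log$recall[i])
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
      }
    }
  }
  invisible(path)
}

#' Remove learners observed under more than one trial arm
#'
#' Learners who reinstalled the app could be re-randomized to a different
#' arm; the observable consequence is a learner appearing under two arm
#' labels. Such learners are removed entirely.
#'
#' @param log a [review_log()].
#' @return the filtered log; the number of removed learners is available in
#'   `attr(, "metadata")$removed_arm_switchers`.
#' @export
filter_arm_switchers <- function(log) {
  stopifnot(inherits(log, "review_log"))
  if (nrow(log) == 0) return(log)
  n_arms <- tapply(log$arm, log$learner_id, function(a) length(unique(a)))
  switchers <- names(n_arms)[n_arms > 1L]
  keep <- !(log$learner_id %in% switchers)
  meta <- attr(log, "metadata")
  meta$removed_arm_switchers <- length(switchers)
  review_log(tibble::as_tibble(log)[keep, , drop = FALSE], metadata = meta)
}

#' Remove learners with too little usage
#'
#' Learners cramming immediately before a test are not expected to benefit
#' from any sequencing algorithm; those whose usage span (first to last
#' event) is below `min_days` are removed. The boundary is inclusive: a
#' span of exactly `min_days` is retained.
#'
#' @param log a [review_log()].
#' @param min_days minimum usage, in days (default 2).
#' @param measure `"span"` (calendar span first-to-last event, default) or
#'   `"active_days"` (number of distinct calendar days with activity).
#' @return the filtered log; removed-learner count in
#'   `attr(, "metadata")$removed_short_usage`.
#' @export
filter_short_usage <- function(log, min_days = 2,
                               measure = c("span", "active_days")) {
  stopifnot(inherits(log, "review_log"))
  measure <- match.arg(measure)
  assert_scalar_number(min_days, "min_days", lower = 0)
  if (nrow(log) == 0) return(log)
  usage <- if (measure == "span") {
    tapply(log$time, log$learner_id, function(t) max(t) - min(t))
  } else {
    tapply(log$time, log$learner_id, function(t) length(unique(floor(t))))
  }
  short <- names(usage)[usage < min_days]
  keep <- !(log$learner_id %in% short)
  meta <- attr(log, "metadata")
  meta$removed_short_usage <- length(short)
  review_log(tibble::as_tibble(log)[keep, , drop = FALSE], metadata = meta)
}

#' Split a review log into per-(learner, question) review sequences
#'
#' Each unique (learner, question) pair keys one time-ordered sequence of
#' its review events; the sequences partition the log.
#'
#' @param log a [review_log()].
#' @return a nested tibble with one row per (learner_id, question_id), a
#'   list-column `events` of per-pair event tibbles (time-ordered), and
#'   `n_events` counts.
#' @export
build_sequences <- function(log) {
  stopifnot(inherits(log, "review_log"))
  events <- tibble::as_tibble(log)
  if (nrow(events) == 0) {
    return(tibble::tibble(learner_id = character(), question_id = character(),
                          n_events = integer(), events = list()))
  }
  events |>
    dplyr::group_by(.data$learner_id, .data$question_id) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(n_events = dplyr::n(),
                     events = list(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}

#' Read a review log exported by the released trial-data repository
#'
#' Adapter mapping a foreign column naming onto the canonical schema of
#' [read_review_log()]. Defaults cover the obvious renamings
#' (`user_id`/`learner`, `item_id`/`question`, `timestamp`, `result`/
#' `correct`, `group`); pass `columns` to override for the actual export at
#' hand. Times are interpreted as epoch seconds.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping canonical names
#'   (`learner_id`, `question_id`, `session_id`, `time`, `recall`, `arm`)
#'   to the file's column names; canonical names absent from the mapping
#'   are auto-detected from common synonyms.
#' @return a [review_log()].
#' @export
read_trial_export <- function(path, columns = character()) {
  synonyms <- list(
    learner_id = c("learner_id", "user_id", "user", "learner"),
    question_id = c("question_id", "item_id", "item", "question"),
    session_id = c("session_id", "session"),
    time = c("time", "timestamp", "ts"),
    recall = c("recall", "result", "correct", "outcome"),
    arm = c("arm", "group", "condition"))
  raw <- utils::read.csv(path, colClasses = "character",
                         encoding = "UTF-8")
  resolved <- vapply(names(synonyms), function(canon) {
    if (canon %in% names(columns)) return(unname(columns[[canon]]))
    hit <- intersect(synonyms[[canon]], names(raw))
    if (length(hit) == 0) {
      if (canon == "session_id") return(NA_character_)
      abort(sprintf("%s: cannot locate a column for '%s'", path, canon),
            class = "spacedselect_schema_error")
    }
    hit[[1]]
  }, character(1))
  events <- tibble::tibble(
    learner_id = raw[[resolved[["learner_id"]]]],
    question_id = raw[[resolved[["question_id"]]]],
    session_id = if (is.na(resolved[["session_id"]])) {
      paste(raw[[resolved[["learner_id"]]]], raw[[resolved[["time"]]]],
            sep = "@")
    } else raw[[resolved[["session_id"]]]],
    time = as.numeric(raw[[resolved[["time"]]]]) / SECONDS_PER_DAY,
    recall = as.integer(as.numeric(raw[[resolved[["recall"]]]])),
    arm = tolower(raw[[resolved[["arm"]]]]))
  events$arm[!(events$arm %in% ARM_LEVELS)] <- "unknown"
  review_log(events, metadata = list(source = path, adapter = "trial_export"))
}
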