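#' Validate and normalize a pipeline run configuration
#'
#' Fills defaults, checks ranges, and rejects unknown keys. The
#' configuration mirrors the pipeline stages: a `population` block (see
#' [population_config()]), a `fit` block (`l2`), an `evaluation` block
#' (`epsilon`, `n_t_bins`, `n_reviews_min`, `n_reviews_max`,
#' `alpha_level`, `n0_method`), plus a root `seed`.
#'
#' @param raw a named list (e.g. parsed from JSON) or a JSON file path.
#' @return a validated `run_config` list with every default filled in.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  if (!is.list(raw)) abort("config must be a named list or JSON object")
  known_top <- c("population", "fit", "evaluation", "seed", "out_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "spacedselect_config_error")
  }
  seed <- raw$seed %||% 1L
  assert_scalar_number(seed, "seed")

  pop_raw <- raw$population %||% list()
  pop_known <- setdiff(names(formals(population_config)), "seed")
  unknown <- setdiff(names(pop_raw), pop_known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown population key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "spacedselect_config_error")
  }
  population <- do.call(population_config,
                        c(pop_raw, list(seed = as.integer(seed))))

  fit_raw <- raw$fit %||% list()
  unknown <- setdiff(names(fit_raw), "l2")
  if (length(unknown) > 0) {
    abort(sprintf("unknown fit key(s): %s", paste(unknown, collapse = ", ")),
          class = "spacedselect_config_error")
  }
  fit <- list(l2 = fit_raw$l2 %||% 1e-3)
  assert_scalar_number(fit$l2, "fit.l2", lower = 0)

  eval_raw <- raw$evaluation %||% list()
  eval_known <- c("epsilon", "n_t_bins", "n_reviews_min", "n_reviews_max",
                  "alpha_level", "n0_method")
  unknown <- setdiff(names(eval_raw), eval_known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown evaluation key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "spacedselect_config_error")
  }
  evaluation <- modifyList(
    list(epsilon = 0.01, n_t_bins = 3, n_reviews_min = 2, n_reviews_max = 7,
         alpha_level = 0.05, n0_method = "fitted"), eval_raw)
  assert_scalar_number(evaluation$epsilon, "evaluation.epsilon",
                       lower = 0, strict_lower = TRUE, upper = 0.5)
  assert_scalar_number(evaluation$n_t_bins, "evaluation.n_t_bins", lower = 1)
  assert_scalar_number(evaluation$alpha_level, "evaluation.alpha_level",
                       lower = 0, upper = 1)
  if (!(evaluation$n0_method %in% c("fitted", "empirical"))) {
    abort("evaluation.n0_method must be 'fitted' or 'empirical'",
          class = "spacedselect_config_error")
  }
  structure(list(population = population, fit = fit,
                 evaluation = evaluation, seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end in-silico trial pipeline
#'
#' simulate -> fit (on the simulated log) -> evaluate, persisting every
#' artifact plus a provenance record (config hash, seed, package version)
#' into `out_dir`: `log.csv`, `truth.json`, `model.json`, `report.json`,
#' `provenance.json`. Re-running with the same configuration reproduces
#' identical artifacts.
#'
#' @param config a `run_config` from [validate_config()] (or a raw list /
#'   JSON path, validated on the fly).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `log`, `truth`, `params`
#'   (fitted), `report`, and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "spacedselect_stage_error")
    })
  }
  sim <- stage("simulate", simulate_trial(config$population))
  stage("write-log", write_review_log(sim$log, file.path(out_dir, "log.csv")))
  stage("write-truth", write_ground_truth(sim$truth,
                                          file.path(out_dir, "truth.json")))
  obs <- stage("observations", recall_observations(sim$log)$observations)
  params <- stage("fit", fit_hlr(obs, l2 = config$fit$l2))
  stage("write-model", write_hlr_params(params,
                                        file.path(out_dir, "model.json")))
  ev <- config$evaluation
  report <- stage("evaluate", evaluate_trial(
    sim$log, epsilon = ev$epsilon,
    n_reviews_range = seq(ev$n_reviews_min, ev$n_reviews_max),
    n_t_bins = ev$n_t_bins, alpha_level = ev$alpha_level,
    n0_method = ev$n0_method))
  report_json <- list(
    summary = report$comparison$summary,
    cells = report$comparison$cells,
    contrasts = report$comparison$contrasts,
    regressions = report$regressions,
    engagement_per_arm = report$engagement$per_arm,
    engagement_relative_to_random = as.list(
      report$engagement$relative_to_random),
    fitted = list(alpha = params$alpha, beta = params$beta),
    epsilon = ev$epsilon)
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  config_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                                  digits = NA)
  provenance <- list(
    config_hash = fnv1a_hash(as.character(config_json)),
    seed = config$seed,
    package = "spacedselect",
    version = as.character(utils::packageVersion("spacedselect")),
    config = jsonlite::fromJSON(config_json, simplifyVector = TRUE),
    artifacts = c("log.csv", "truth.json", "model.json", "report.json"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(log = sim$log, truth = sim$truth, params = params,
                 report = report,
                 paths = file.path(out_dir, c("log.csv", "truth.json",
                                              "model.json", "report.json",
                                              "provenance.json"))))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
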