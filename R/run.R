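#' Run a complete flux-estimation analysis
#'
#' End-to-end pipeline behind the command-line interface: reads a (possibly
#' multi-experiment) time-course TSV, fits the chosen model to each
#' experiment, runs the Monte-Carlo uncertainty analysis and the
#' goodness-of-fit statistics, and writes the five run artifacts per
#' experiment under `output_dir/<experiment>/` — `results.tsv`,
#' `stats.txt`, `config.yaml`, `plot.pdf` + `plot.svg`, and `exflux.log` —
#' plus an aggregate `results.tsv`, the effective `config.yaml` and a run
#' log at the root of `output_dir`.
#'
#' Settings can come from a [run_config()] (e.g. one emitted by a previous
#' run) and/or from the explicit arguments; explicit arguments override the
#' config, which overrides package defaults. With a seed, experiment `i`
#' is fitted under seed `seed + i - 1`, making the whole run — including
#' the emitted results file — byte-for-byte reproducible when replayed
#' from the written `config.yaml`.
#'
#' A failing experiment is logged and skipped; the remaining experiments
#' are still fitted and written.
#'
#' @param data_path Path to the input TSV (see [read_timecourse()]).
#' @param config Optional [run_config()].
#' @param model,sds,parameters,mc_iterations,seed,alpha Overrides of the
#'   corresponding config fields (see [fit_growth()]).
#' @param output_dir Output directory (default from config, else
#'   `"exflux_results"`).
#' @param model_file Optional path to a user model file
#'   ([load_model_file()]); registered before fitting.
#' @param verbose Keep DEBUG messages in the log.
#' @return Invisibly, a list with `fits` (named by experiment), `results`
#'   (aggregate tibble), `reports`, `failures` (character vector of failed
#'   experiment labels) and `output_dir`.
#' @export
run_experiments <- function(data_path, config = NULL, model = NULL, sds = NULL,
                            parameters = NULL, mc_iterations = NULL, seed = NULL,
                            alpha = NULL, output_dir = NULL, model_file = NULL,
                            verbose = FALSE) {
  if (!is.null(model_file)) {
    loaded <- load_model_file(model_file, overwrite = TRUE)
    if (is.null(model)) model <- loaded$name
  }
  eff <- effective_config(config, model = model, sds = sds,
                          parameters = parameters, mc_iterations = mc_iterations,
                          seed = seed, alpha = alpha, output_dir = output_dir)
  datasets <- read_timecourse(data_path)
  dir.create(eff$output_dir, recursive = TRUE, showWarnings = FALSE)
  logger <- setup_logger(eff$output_dir, verbose = verbose)
  log_msg(logger, "INFO", "input: %s (%d experiment(s)); model: %s; mc_iterations: %d; seed: %s",
          data_path, length(datasets), eff$model, eff$mc_iterations,
          if (is.null(eff$seed)) "none" else eff$seed)
  write_run_config(eff, file.path(eff$output_dir, "config.yaml"))

  fits <- list()
  reports <- list()
  failures <- character()
  for (i in seq_along(datasets)) {
    label <- names(datasets)[i]
    exp_seed <- if (is.null(eff$seed)) NULL else eff$seed + i - 1L
    fit <- tryCatch(
      withCallingHandlers(
        fit_growth(datasets[[i]], eff$model, sds = eff$sds,
                   parameters = eff$parameters, mc_iterations = eff$mc_iterations,
                   seed = exp_seed, alpha = eff$alpha, experiment = label),
        exflux_bound_warning = function(w) {
          log_msg(logger, "INFO", "[%s] %s", label, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        log_msg(logger, "INFO", "[%s] FAILED: %s", label, conditionMessage(e))
        NULL
      })
    if (is.null(fit)) {
      failures <- c(failures, label)
      next
    }
    log_msg(logger, "INFO",
            "[%s] objective %.6g after %d DE generations (%d evals, %d simulation failures); MC failures: %s",
            label, fit$objective_value, fit$diagnostics$de$iterations,
            fit$diagnostics$de$nfev, fit$diagnostics$sim_failures,
            if (is.null(fit$mc)) "skipped" else fit$mc$n_failed)
    fits[[label]] <- fit
    reports[[label]] <- stat_report(fit)
    write_experiment_artifacts(fit, file.path(eff$output_dir, label), eff,
                               verbose = verbose)
  }
  results <- if (length(fits)) write_results_tsv(fits, file.path(eff$output_dir, "results.tsv")) else NULL
  if (length(reports)) {
    write_stats_report(dplyr::bind_rows(reports), file.path(eff$output_dir, "stats.txt"))
  }
  log_msg(logger, "INFO", "done: %d fitted, %d failed", length(fits), length(failures))
  invisible(list(fits = fits, results = results,
                 reports = if (length(reports)) dplyr::bind_rows(reports) else NULL,
                 failures = failures, output_dir = eff$output_dir))
}

write_experiment_artifacts <- function(fit, dir, eff, verbose = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exp_logger <- setup_logger(dir, verbose = verbose)
  log_msg(exp_logger, "INFO", "experiment '%s', model '%s': objective %.6g, %d observations, %d free parameters",
          fit$dataset$experiment, fit$model$name, fit$objective_value,
          fit$n_data, fit$n_params)
  if (length(fit$diagnostics$at_bound)) {
    log_msg(exp_logger, "INFO", "parameters at a bound: %s",
            paste(fit$diagnostics$at_bound, collapse = ", "))
  }
  if (!is.null(fit$mc)) {
    log_msg(exp_logger, "INFO", "Monte-Carlo: %d iterations, %d failed",
            fit$mc$n_requested, fit$mc$n_failed)
  }
  write_results_tsv(fit, file.path(dir, "results.tsv"))
  write_stats_report(stat_report(fit), file.path(dir, "stats.txt"))
  write_run_config(eff, file.path(dir, "config.yaml"))
  write_plots(fit, file.path(dir, "plot"))
  invisible(dir)
}

effective_config <- function(config, model, sds, parameters, mc_iterations,
                             seed, alpha, output_dir) {
  if (!is.null(config)) stopifnot(inherits(config, "run_config"))
  pick <- function(arg, field, default) arg %||% (if (!is.null(config)) config[[field]] else NULL) %||% default
  model <- pick(model, "model", NULL)
  sds <- pick(sds, "sds", NULL)
  if (is.null(model)) {
    rlang::abort("a model must be given (argument, config, or model file)",
                 class = "exflux_input_error")
  }
  if (is.null(sds) || !length(sds)) {
    rlang::abort("measurement sds must be given (argument or config)",
                 class = "exflux_input_error")
  }
  run_config(model = model, sds = sds,
             parameters = pick(parameters, "parameters", list()),
             mc_iterations = pick(mc_iterations, "mc_iterations", 100L),
             seed = pick(seed, "seed", NULL),
             alpha = pick(alpha, "alpha", 0.05),
             output_dir = pick(output_dir, "output_dir", "exflux_results"))
}

#' Fit and rank several candidate models on the same data
#'
#' Fits each named model to every experiment in the input, writes per-model
#' artifacts under `output_dir/<experiment>/<model>/`, and writes an
#' AICc-sorted ranking (`ranking.tsv`, with `delta_aic` and
#' `similar_support` columns) per experiment. Within an experiment every
#' model is fitted under the same seed so rankings compare like with like.
#'
#' @inheritParams run_experiments
#' @param models Character vector of two or more registered model names.
#' @return Invisibly, a list with `rankings` (tibble with an `experiment`
#'   column), `fits` (nested list), `failures` and `output_dir`.
#' @export
compare_models <- function(data_path, models, config = NULL, sds = NULL,
                           parameters = NULL, mc_iterations = NULL, seed = NULL,
                           alpha = NULL, output_dir = NULL, verbose = FALSE) {
  if (length(models) < 2L) {
    rlang::abort("model comparison needs at least two model names",
                 class = "exflux_input_error")
  }
  eff <- effective_config(config, model = models[1], sds = sds,
                          parameters = parameters,
                          mc_iterations = mc_iterations %||% 0L,
                          seed = seed, alpha = alpha, output_dir = output_dir)
  datasets <- read_timecourse(data_path)
  dir.create(eff$output_dir, recursive = TRUE, showWarnings = FALSE)
  logger <- setup_logger(eff$output_dir, verbose = verbose)
  rankings <- list()
  all_fits <- list()
  failures <- character()
  for (i in seq_along(datasets)) {
    label <- names(datasets)[i]
    exp_seed <- if (is.null(eff$seed)) NULL else eff$seed + i - 1L
    fits <- list()
    for (m in models) {
      fit <- tryCatch(
        suppressWarnings(
          fit_growth(datasets[[i]], m, sds = eff$sds, parameters = eff$parameters,
                     mc_iterations = eff$mc_iterations, seed = exp_seed,
                     alpha = eff$alpha, experiment = label)),
        error = function(e) {
          log_msg(logger, "INFO", "[%s/%s] FAILED: %s", label, m, conditionMessage(e))
          NULL
        })
      if (is.null(fit)) {
        failures <- c(failures, paste(label, m, sep = "/"))
        next
      }
      fits[[m]] <- fit
      write_experiment_artifacts(fit, file.path(eff$output_dir, label, m), eff,
                                 verbose = verbose)
    }
    all_fits[[label]] <- fits
    if (length(fits) >= 2L) {
      rk <- rank_models(fits)
      readr::write_tsv(rk, file.path(eff$output_dir, label, "ranking.tsv"), na = "")
      rankings[[label]] <- dplyr::mutate(rk, experiment = label)
    }
  }
  rankings <- if (length(rankings)) dplyr::bind_rows(rankings) else NULL
  if (!is.null(rankings)) {
    readr::write_tsv(rankings, file.path(eff$output_dir, "ranking.tsv"), na = "")
  }
  log_msg(logger, "INFO", "comparison done: %d experiment(s), %d failure(s)",
          length(datasets), length(failures))
  invisible(list(rankings = rankings, fits = all_fits, failures = failures,
                 output_dir = eff$output_dir))
}
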