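#' Write fitted fluxes and growth parameters to a TSV file
#'
#' Long format, one row per (experiment, parameter), with columns
#' `experiment`, `model`, `parameter`, `optimal`, `mc_mean`, `mc_sd`,
#' `ci_2.5`, `ci_97.5`. Rows follow the input order of the fits and, within
#' a fit, the model's parameter order. Missing Monte-Carlo statistics (run
#' skipped, or fixed parameters) are written as empty cells. Numbers are
#' written at full double precision so the file round-trips losslessly.
#'
#' @param fits A `flux_fit` or list of them.
#' @param path Output path.
#' @return The results tibble, invisibly.
#' @export
write_results_tsv <- function(fits, path) {
  res <- results_table(fits)
  # 17 significant digits guarantee exact double round-trip through text
  out <- dplyr::mutate(res, dplyr::across(
    dplyr::where(is.numeric),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  readr::write_tsv(out, path, na = "")
  invisible(res)
}

#' @rdname write_results_tsv
#' @export
results_table <- function(fits) {
  if (inherits(fits, "flux_fit")) fits <- list(fits)
  if (!length(fits)) {
    rlang::abort("no fits to write", class = "exflux_input_error")
  }
  dplyr::bind_rows(lapply(fits, function(fit) {
    td <- tidy(fit)
    tibble::tibble(experiment = fit$dataset$experiment, model = fit$model$name,
                   parameter = td$parameter, optimal = td$estimate,
                   mc_mean = td$mc_mean, mc_sd = td$mc_sd,
                   `ci_2.5` = td$ci_lower, `ci_97.5` = td$ci_upper)
  }))
}

#' Read back a results TSV
#'
#' @param path Path written by [write_results_tsv()].
#' @return Tibble with the same columns and full-precision values.
#' @export
read_results_tsv <- function(path) {
  # numeric cells are re-parsed with strtod (correctly rounded), so values
  # written by write_results_tsv come back bit-identical
  raw <- readr::read_tsv(path, na = "", show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (cn in setdiff(names(raw), c("experiment", "model", "parameter"))) {
    raw[[cn]] <- as.numeric(raw[[cn]])
  }
  raw
}

#' Write the statistical report
#'
#' Plain-text summary per experiment and model: chi-squared statistic,
#' degrees of freedom, p-value, verdict at the chosen significance level,
#' AIC and AICc. When several models were fitted to the same experiment, an
#' AICc ranking table with `delta_aic` and similar-support flags is
#' appended.
#'
#' @param reports A data frame of [stat_report()] rows, or a list of
#'   `flux_fit` objects.
#' @param path Output path.
#' @return The report tibble, invisibly.
#' @export
write_stats_report <- function(reports, path) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- dplyr::bind_rows(lapply(reports, function(r) {
      if (inherits(r, "flux_fit")) stat_report(r) else tibble::as_tibble(r)
    }))
  }
  reports <- tibble::as_tibble(reports)
  lines <- c("Goodness-of-fit and model comparison", "")
  for (exp in unique(reports$experiment)) {
    sub <- reports[reports$experiment == exp, , drop = FALSE]
    lines <- c(lines, sprintf("Experiment: %s", exp))
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines,
                 sprintf("  Model: %s", r$model),
                 sprintf("    chi2 statistic : %.6g", r$chi2_stat),
                 sprintf("    degrees of freedom : %d", r$dof),
                 sprintf("    p-value : %.6g", r$p_value),
                 sprintf("    verdict at alpha=%g : %s", r$alpha, r$verdict),
                 sprintf("    AIC : %.6g", r$aic),
                 if (is.na(r$aicc)) "    AICc : not defined (too few observations)"
                 else sprintf("    AICc : %.6g", r$aicc))
    }
    if (nrow(sub) > 1L) {
      rk <- rank_models(sub)
      tab <- rk[c("model", "aic", "aicc", "delta_aic", "similar_support")]
      lines <- c(lines, "  Model ranking (AICc ascending):",
                 paste0("    ", utils::capture.output(print.data.frame(
                   as.data.frame(tab), row.names = FALSE))))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(reports)
}

# ---- logging ------------------------------------------------------------

#' Plain-text run logger
#'
#' Creates `exflux.log` in `output_dir` and returns a logger handle.
#' Messages are timestamped; `DEBUG` messages are kept only when
#' `verbose = TRUE`.
#'
#' @param output_dir Directory for the log file (created if needed).
#' @param verbose Keep DEBUG-level messages.
#' @param echo Also print messages to the console.
#' @return A logger object for [log_msg()].
#' @export
setup_logger <- function(output_dir, verbose = FALSE, echo = FALSE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(output_dir, "exflux.log")
  cat("", file = path)
  logger <- list(path = path, verbose = verbose, echo = echo)
  class(logger) <- "exflux_logger"
  log_msg(logger, "INFO", "exflux %s | R %s",
          as.character(utils::packageVersion("exflux")),
          paste(R.version$major, R.version$minor, sep = "."))
  logger
}

#' @rdname setup_logger
#' @param logger Logger from [setup_logger()].
#' @param level `"INFO"` or `"DEBUG"`.
#' @param fmt,... [sprintf()] message.
#' @export
log_msg <- function(logger, level, fmt, ...) {
  if (is.null(logger)) return(invisible(NULL))
  if (level == "DEBUG" && !logger$verbose) return(invisible(NULL))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = logger$path, append = TRUE)
  if (logger$echo) message(line)
  invisible(NULL)
}
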