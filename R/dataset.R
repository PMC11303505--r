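#' Build a time-course dataset for fitting
#'
#' Wraps a table of measured concentrations together with the per-variable
#' measurement standard deviations the weighted least-squares objective
#' needs. The table must contain a `time` column (h), a biomass column `X`,
#' and one numeric column per extracellular metabolite. Missing observations
#' (`NA`) are allowed anywhere as long as every measured variable keeps at
#' least two observations; they contribute nothing to the objective.
#'
#' @param data Data frame with columns `time`, `X` and metabolite columns.
#' @param sds Named numeric vector (or list) of measurement standard
#'   deviations, one per measured variable (`X` and each metabolite). A
#'   single unnamed value is recycled to all variables. All sds must be > 0.
#' @param experiment Optional experiment label (used in batch outputs).
#' @return An object of class `timecourse_dataset`: a list with elements
#'   `data` (tibble), `metabolites`, `sds` and `experiment`.
#' @export
timecourse_dataset <- function(data, sds, experiment = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("time", "X") %in% names(data))) {
    rlang::abort("dataset needs columns 'time' and 'X'", class = "exflux_schema_error")
  }
  if ("experiments" %in% names(data)) {
    if (is.null(experiment) && dplyr::n_distinct(data$experiments) == 1L) {
      experiment <- as.character(data$experiments[1])
    }
    data$experiments <- NULL
  }
  non_num <- names(data)[!vapply(data, is.numeric, TRUE)]
  if (length(non_num)) {
    rlang::abort(sprintf("non-numeric columns in dataset: %s",
                         paste(non_num, collapse = ", ")),
                 class = "exflux_parse_error")
  }
  if (anyNA(data$time)) {
    rlang::abort("'time' must not contain missing values", class = "exflux_validation_error")
  }
  data <- dplyr::arrange(data, .data$time)
  if (anyDuplicated(data$time)) {
    rlang::abort("duplicate time points within one experiment", class = "exflux_validation_error")
  }
  metabolites <- setdiff(names(data), c("time", "X"))
  measured <- c("X", metabolites)
  n_obs <- vapply(measured, function(v) sum(!is.na(data[[v]])), 0L)
  if (any(n_obs < 2L)) {
    rlang::abort(sprintf("each fitted variable needs at least 2 observations (violated: %s)",
                         paste(measured[n_obs < 2L], collapse = ", ")),
                 class = "exflux_validation_error")
  }
  sds <- normalize_sds(sds, measured)
  structure(list(data = data, metabolites = metabolites, sds = sds,
                 experiment = experiment %||% "experiment"),
            class = "timecourse_dataset")
}

normalize_sds <- function(sds, measured) {
  sds <- unlist(sds)
  if (length(sds) == 1L && is.null(names(sds))) {
    sds <- stats::setNames(rep(sds, length(measured)), measured)
  }
  if (is.null(names(sds)) || !all(measured %in% names(sds))) {
    rlang::abort(sprintf("`sds` must name every measured variable: %s",
                         paste(measured, collapse = ", ")),
                 class = "exflux_input_error")
  }
  sds <- sds[measured]
  if (anyNA(sds) || any(sds <= 0)) {
    rlang::abort("all measurement sds must be > 0", class = "exflux_input_error")
  }
  sds
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat("<timecourse_dataset> '", x$experiment, "': ", nrow(x$data), " time points, ",
      length(x$metabolites), " metabolite(s)",
      if (length(x$metabolites)) paste0(" (", paste(x$metabolites, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read a tab-separated time-course file
#'
#' Input dialect: UTF-8 TSV with a header row; required columns `time` and
#' `X` (case-sensitive); every other numeric column is treated as an
#' extracellular metabolite; an optional `experiments` column splits the rows
#' into one dataset per label for batch runs. Empty cells and `NA` encode
#' missing observations. CRLF line endings and a missing trailing newline are
#' tolerated; comma-delimited files are rejected with a pointed message.
#'
#' @param path Path to the TSV file.
#' @return A named list of tibbles, one per experiment label (a single
#'   element named `"experiment"` when the `experiments` column is absent),
#'   each sorted by time.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("input file '%s' does not exist", path),
                 class = "exflux_schema_error")
  }
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) {
    rlang::abort(sprintf("'%s' looks comma-delimited; the input must be tab-separated (tsv)", path),
                 class = "exflux_schema_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  if (!all(c("time", "X") %in% names(raw))) {
    rlang::abort(sprintf("'%s' must contain columns 'time' and 'X' (found: %s)",
                         path, paste(names(raw), collapse = ", ")),
                 class = "exflux_schema_error")
  }
  labels <- if ("experiments" %in% names(raw)) as.character(raw$experiments) else
    rep("experiment", nrow(raw))
  if (anyNA(labels)) {
    rlang::abort(sprintf("'%s': empty cells in the 'experiments' column", path),
                 class = "exflux_validation_error")
  }
  value_cols <- setdiff(names(raw), "experiments")
  parsed <- raw
  for (cn in value_cols) {
    vals <- raw[[cn]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      rlang::abort(sprintf("'%s': non-numeric value '%s' at row %d, column '%s'",
                           path, vals[bad[1]], bad[1], cn),
                   class = "exflux_parse_error")
    }
    parsed[[cn]] <- num
  }
  parsed$experiments <- NULL
  out <- lapply(split(seq_len(nrow(parsed)), factor(labels, levels = unique(labels))),
                function(idx) {
                  d <- dplyr::arrange(parsed[idx, , drop = FALSE], .data$time)
                  if (anyNA(d$time)) {
                    rlang::abort(sprintf("'%s': missing values in 'time'", path),
                                 class = "exflux_validation_error")
                  }
                  if (anyDuplicated(d$time)) {
                    rlang::abort(sprintf("'%s': duplicate time points within one experiment", path),
                                 class = "exflux_validation_error")
                  }
                  d
                })
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
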