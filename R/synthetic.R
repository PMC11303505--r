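#' Reference ground-truth parameters for the built-in models
#'
#' Fixed, realistic parameter sets used as the default ground truth of the
#' synthetic-data generator: an *E. coli*-like batch culture growing on a
#' single carbon source (default column name `glc`), inoculated at
#' 0.02 gDW/L, with growth rates around 0.6-0.8 1/h, an initial substrate
#' pool of 15-20 mM, uptake fluxes of 3-4 mmol/gDW/h and, where the model
#' has them, a 1 h lag and a 0.05 1/h abiotic degradation constant. Values
#' are chosen so concentrations stay non-negative over the default 8 h
#' observation window and every parameter lies inside the model's default
#' bounds.
#'
#' @param model Built-in model name.
#' @param metabolite Metabolite column name to use.
#' @return Named numeric parameter vector.
#' @export
builtin_truth <- function(model, metabolite = "glc") {
  m <- metabolite
  base <- c(X0 = 0.02, mu = 0.6)
  met0 <- stats::setNames(20, paste0(m, "_0"))
  switch(model,
    exponential = c(base, met0, stats::setNames(-4, paste0("q_", m))),
    exponential_lag = c(base, t_lag = 1, met0, stats::setNames(-4, paste0("q_", m))),
    exponential_degradation = c(base, met0,
                                stats::setNames(c(-3, 0.05), paste0(c("q_", "k_"), m))),
    exponential_lag_degradation = c(base, t_lag = 1, met0,
                                    stats::setNames(c(-3, 0.05), paste0(c("q_", "k_"), m))),
    monod = c(X0 = 0.05, mu_max = 0.8, Km = 2, yield = 0.4,
              stats::setNames(15, paste0(m, "_0"))),
    rlang::abort(sprintf("no reference truth for model '%s'", model),
                 class = "exflux_input_error")
  )
}

#' Specify a synthetic time-course dataset
#'
#' Describes how to simulate datasets with known ground truth: the
#' generating model and parameters, the sampling grid (default 12 points
#' over 0-8 h), per-variable Gaussian noise standard deviations (0 =
#' noiseless) and a seed. The same spec always generates the same data.
#'
#' @param model Registered model name.
#' @param true_params Named parameter vector (defaults to
#'   [builtin_truth()]).
#' @param times Sampling times (h).
#' @param noise_sds Per-variable noise sd: a named vector over `X` and the
#'   metabolites, or one value recycled to all variables.
#' @param seed Integer seed or `NULL`.
#' @param n_replicates Number of independent replicate datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model, true_params = builtin_truth(model),
                           times = seq(0, 8, length.out = 12),
                           noise_sds = 0, seed = NULL, n_replicates = 1L) {
  true_params <- check_params(true_params)
  check_times(times)
  mets <- infer_metabolites(true_params)
  vars <- c("X", mets)
  noise_sds <- unlist(noise_sds)
  if (length(noise_sds) == 1L && is.null(names(noise_sds))) {
    noise_sds <- stats::setNames(rep(noise_sds, length(vars)), vars)
  }
  if (!all(vars %in% names(noise_sds))) {
    rlang::abort(sprintf("`noise_sds` must cover variables: %s",
                         paste(vars, collapse = ", ")),
                 class = "exflux_input_error")
  }
  if (any(noise_sds < 0)) {
    rlang::abort("`noise_sds` must be non-negative", class = "exflux_input_error")
  }
  structure(list(model = model, true_params = true_params, times = times,
                 metabolites = mets, noise_sds = noise_sds[vars],
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "synthetic_spec")
}

#' Generate synthetic dataset(s) with known ground truth
#'
#' Simulates the true trajectory of the spec's model, then adds independent
#' Gaussian noise per variable. Reproducible under the spec's seed;
#' replicates draw consecutive, independent noise from the same stream.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (a tibble, or a list of tibbles when
#'   `n_replicates > 1`), `truth` (the generating parameters) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  truth_mat <- simulate_raw(get_model(spec$model), spec$true_params,
                            spec$times, spec$metabolites)
  one <- function() {
    noisy <- truth_mat + matrix(
      stats::rnorm(length(truth_mat), 0, rep(spec$noise_sds, each = nrow(truth_mat))),
      nrow = nrow(truth_mat))
    colnames(noisy) <- colnames(truth_mat)
    tibble::as_tibble(as.data.frame(noisy)) |>
      dplyr::mutate(time = spec$times, .before = 1L)
  }
  data <- if (spec$n_replicates == 1L) one() else
    replicate(spec$n_replicates, one(), simplify = FALSE)
  list(data = data, truth = spec$true_params, spec = spec)
}

#' Generate a multi-experiment synthetic batch on disk
#'
#' Emulates a high-throughput flux study: `n_experiments` experiments are
#' simulated from per-experiment ground truths obtained by jittering the
#' base parameters uniformly within given ranges, then written as a single
#' multi-experiment TSV (with an `experiments` column, readable by
#' [read_timecourse()]) plus a ground-truth sidecar TSV with one row per
#' (experiment, parameter).
#'
#' @param n_experiments Number of experiments.
#' @param spec Base [synthetic_spec()] (its seed drives the whole batch).
#' @param jitter Named list of length-2 ranges; each experiment draws those
#'   parameters uniformly within their range.
#' @param dir Output directory.
#' @return Invisibly, a list with `data_path`, `truth_path` and the
#'   ground-truth tibble.
#' @export
generate_batch <- function(n_experiments, spec, jitter = list(), dir = ".") {
  stopifnot(inherits(spec, "synthetic_spec"), n_experiments >= 1)
  unknown <- setdiff(names(jitter), names(spec$true_params))
  if (length(unknown)) {
    rlang::abort(sprintf("jitter refers to unknown parameters: %s",
                         paste(unknown, collapse = ", ")),
                 class = "exflux_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  labels <- sprintf("exp_%03d", seq_len(n_experiments))
  rows <- vector("list", n_experiments)
  truths <- vector("list", n_experiments)
  model <- get_model(spec$model)
  for (i in seq_len(n_experiments)) {
    pars <- spec$true_params
    for (nm in names(jitter)) {
      pars[[nm]] <- stats::runif(1L, jitter[[nm]][1], jitter[[nm]][2])
    }
    mat <- simulate_raw(model, pars, spec$times, spec$metabolites)
    mat <- mat + matrix(stats::rnorm(length(mat), 0,
                                     rep(spec$noise_sds, each = nrow(mat))),
                        nrow = nrow(mat))
    rows[[i]] <- tibble::as_tibble(as.data.frame(mat)) |>
      dplyr::mutate(time = spec$times, experiments = labels[i], .before = 1L)
    truths[[i]] <- tibble::tibble(experiment = labels[i],
                                  parameter = names(pars), value = unname(pars))
  }
  data_path <- file.path(dir, "batch_timecourse.tsv")
  truth_path <- file.path(dir, "batch_ground_truth.tsv")
  readr::write_tsv(dplyr::bind_rows(rows), data_path, na = "")
  truth <- dplyr::bind_rows(truths)
  readr::write_tsv(truth, truth_path, na = "")
  invisible(list(data_path = data_path, truth_path = truth_path, truth = truth))
}
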