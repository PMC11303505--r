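#' Monte-Carlo uncertainty analysis (parametric bootstrap)
#'
#' Quantifies parameter uncertainty by resampling the *fitted* model: each
#' iteration synthesizes a dataset by adding independent Gaussian noise
#' (sd = the dataset's configured per-variable \eqn{\sigma}) to the best-fit
#' simulated values at the observed times, respecting the missingness
#' pattern of the real data, then re-fits the free parameters by bounded
#' quasi-Newton refinement started from the point estimate. The empirical
#' 2.5% and 97.5% percentiles of the resampled estimates give the 95%
#' confidence intervals. Resampled concentrations are deliberately not
#' clipped at zero, preserving the symmetry of the noise model.
#'
#' Iterations whose re-fit fails (simulation error, non-finite objective)
#' are dropped and counted; more than 50% failures aborts the analysis.
#'
#' @param fit A `flux_fit` from [fit_growth()].
#' @param n_iter Number of bootstrap iterations (>= 2).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (so a seeded [fit_growth()] pipeline stays reproducible end to end).
#' @return The `flux_fit` with an `mc` element: `samples` (iterations x free
#'   parameters matrix), `n_requested`, `n_failed`, and `ci` (per-parameter
#'   mean, sd, 2.5% and 97.5% bounds).
#' @export
mc_uncertainty <- function(fit, n_iter = 100L, seed = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  if (n_iter < 2L) {
    rlang::abort("`n_iter` must be at least 2", class = "exflux_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  dataset <- fit$dataset
  obs <- obs_matrix(dataset)
  sds <- dataset$sds[colnames(obs)]
  base <- simulate_raw(fit$model, fit$params, dataset$data$time, dataset$metabolites)
  miss <- is.na(obs)
  ptab <- fit$param_table
  free <- !ptab$fixed
  free_names <- ptab$parameter[free]
  start <- fit$params[free]
  times <- dataset$data$time
  mets <- dataset$metabolites
  full <- fit$params
  sim_obj <- function(free_par, target) {
    full[free] <- free_par
    sim <- tryCatch(simulate_raw(fit$model, full, times, mets),
                    error = function(e) NULL)
    if (is.null(sim) || anyNA(sim) || any(!is.finite(sim))) return(1e100)
    resid <- sweep(target - sim, 2L, sds, `/`)
    min(sum(resid^2, na.rm = TRUE), 1e100)
  }

  samples <- matrix(NA_real_, n_iter, sum(free),
                    dimnames = list(NULL, free_names))
  n_failed <- 0L
  for (b in seq_len(n_iter)) {
    noise <- matrix(stats::rnorm(length(base), mean = 0,
                                 sd = rep(sds, each = nrow(base))),
                    nrow = nrow(base))
    target <- base + noise
    target[miss] <- NA_real_
    res <- polish_lbfgsb(function(p) sim_obj(p, target), start,
                         ptab$lower[free], ptab$upper[free], passes = 3L)
    if (!is.finite(res$value) || res$value >= 1e100) {
      n_failed <- n_failed + 1L
    } else {
      samples[b, ] <- res$par
    }
  }
  if (n_failed > n_iter / 2) {
    rlang::abort(sprintf("Monte-Carlo analysis failed: %d of %d re-fits unusable",
                         n_failed, n_iter),
                 class = "exflux_fit_error")
  }
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  ci <- tibble::tibble(
    parameter = free_names,
    mean = colMeans(samples),
    sd = apply(samples, 2L, stats::sd),
    ci_lower = apply(samples, 2L, stats::quantile, probs = 0.025, names = FALSE),
    ci_upper = apply(samples, 2L, stats::quantile, probs = 0.975, names = FALSE)
  )
  fit$mc <- list(samples = samples, n_requested = as.integer(n_iter),
                 n_failed = n_failed, ci = ci)
  fit
}
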