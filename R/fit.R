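#' Weighted sum of squared errors
#'
#' The fitting objective \eqn{c(p) = \sum_i ((x_i - y_i(p)) / \sigma_i)^2}
#' summed over every non-missing observation of biomass and of every
#' metabolite, where \eqn{x_i} is the measured value, \eqn{\sigma_i} its
#' measurement standard deviation and \eqn{y_i(p)} the model simulation at
#' the same time point. Missing observations contribute nothing.
#'
#' @param params Named numeric vector of model parameters.
#' @param model A `growth_model` or registered model name.
#' @param dataset A [timecourse_dataset()].
#' @return Non-negative scalar objective value.
#' @export
weighted_sse <- function(params, model, dataset) {
  model <- as_growth_model(model)
  stopifnot(inherits(dataset, "timecourse_dataset"))
  obs <- obs_matrix(dataset)
  sim <- simulate_raw(model, check_params(params), dataset$data$time, dataset$metabolites)
  resid <- sweep(obs - sim, 2L, dataset$sds[colnames(obs)], `/`)
  sum(resid^2, na.rm = TRUE)
}

obs_matrix <- function(dataset) {
  vars <- c("X", dataset$metabolites)
  mat <- as.matrix(dataset$data[vars])
  colnames(mat) <- vars
  mat
}

# objective over the free-parameter subvector; simulation failures are
# reported as +Inf so the optimizer routes around them (count kept)
make_objective <- function(model, dataset, ptab, env = new.env()) {
  obs <- obs_matrix(dataset)
  times <- dataset$data$time
  sds <- dataset$sds[colnames(obs)]
  mets <- dataset$metabolites
  full <- stats::setNames(ptab$initial, ptab$parameter)
  free <- !ptab$fixed
  env$n_sim_failures <- 0L
  function(free_par) {
    full[free] <- free_par
    sim <- tryCatch(simulate_raw(model, full, times, mets),
                    error = function(e) NULL)
    if (is.null(sim) || anyNA(sim) || any(!is.finite(sim))) {
      env$n_sim_failures <- env$n_sim_failures + 1L
      return(Inf)
    }
    resid <- sweep(obs - sim, 2L, sds, `/`)
    sum(resid^2, na.rm = TRUE)
  }
}

#' Fit a growth model to time-course data
#'
#' Estimates all free model parameters by minimizing the weighted sum of
#' squared errors ([weighted_sse()]) in two stages: a global search with
#' bounded [differential_evolution()] over the parameter box, followed by
#' bounded quasi-Newton refinement (L-BFGS-B, [stats::optim()]) started from
#' the global stage's best point. The refined optimum never exceeds the
#' global stage's objective. When `mc_iterations > 0` a parametric-bootstrap
#' Monte-Carlo analysis ([mc_uncertainty()]) is appended, giving
#' per-parameter means, standard deviations and 95% confidence intervals.
#'
#' Any parameter may be overridden or fixed through `parameters`, e.g.
#' `parameters = list(mu = list(initial = 0.7), q_glc = list(initial = 0,
#' fixed = TRUE))`. Fixed parameters are excluded from the search, from the
#' parameter count used in statistics and from the bootstrap.
#'
#' With a `seed`, the whole pipeline (global search, refinement,
#' Monte-Carlo) is reproducible end to end.
#'
#' @param data A data frame with columns `time`, `X` and metabolite columns,
#'   or a ready-made [timecourse_dataset()].
#' @param model A `growth_model` or registered model name.
#' @param sds Measurement standard deviations (see [timecourse_dataset()]);
#'   ignored when `data` is already a dataset.
#' @param parameters Named list of per-parameter overrides, each a list with
#'   any of `initial`, `lower`, `upper`, `fixed`.
#' @param mc_iterations Monte-Carlo iterations (0 skips the bootstrap).
#' @param seed Optional integer seed.
#' @param alpha Significance level carried into goodness-of-fit reporting.
#' @param control List of [differential_evolution()] settings overrides
#'   (`popmult`, `mutation`, `recombination`, `tol`, `maxiter`).
#' @param experiment Optional experiment label.
#' @return An object of class `flux_fit`. Use [tidy()][generics::tidy] for
#'   the parameter table, [glance()][generics::glance] for fit statistics,
#'   [ggplot2::autoplot()] for fitted-vs-measured panels.
#' @examples
#' truth <- c(X0 = 0.02, mu = 0.8, glc_0 = 20, q_glc = -8)
#' d <- simulate_model("exponential", truth, seq(0, 8, length.out = 12))
#' fit <- fit_growth(d, "exponential", sds = c(X = 0.01, glc = 0.1),
#'                   mc_iterations = 0, seed = 1)
#' tidy(fit)
#' @export
fit_growth <- function(data, model, sds = NULL, parameters = list(),
                       mc_iterations = 100L, seed = NULL, alpha = 0.05,
                       control = list(), experiment = NULL) {
  model <- as_growth_model(model)
  dataset <- if (inherits(data, "timecourse_dataset")) data else
    timecourse_dataset(data, sds, experiment = experiment)
  check_metabolite_count(model, dataset$metabolites)
  ptab <- resolve_parameters(model, dataset$metabolites, parameters)
  if (!is.null(seed)) set.seed(seed)

  free <- !ptab$fixed
  if (!any(free)) {
    rlang::abort("all parameters are fixed; nothing to fit", class = "exflux_fit_error")
  }
  ctrl <- utils::modifyList(list(popmult = 15, mutation = c(0.5, 1),
                                 recombination = 0.7, tol = 0.01, maxiter = 200),
                            control)
  env <- new.env()
  obj <- make_objective(model, dataset, ptab, env)

  de <- differential_evolution(obj, lower = ptab$lower[free], upper = ptab$upper[free],
                               init = ptab$initial[free],
                               popmult = ctrl$popmult, mutation = ctrl$mutation,
                               recombination = ctrl$recombination,
                               tol = ctrl$tol, maxiter = ctrl$maxiter)
  if (!is.finite(de$value)) {
    rlang::abort(sprintf("global optimization failed for model '%s': every candidate simulation failed (%d failures)",
                         model$name, env$n_sim_failures),
                 class = "exflux_fit_error")
  }
  # refine several candidate basins, not just the DE winner: the DE best,
  # up to two well-separated members of the final population, and the
  # user's initial point (the latter guards against the occasional
  # premature population collapse onto a plateau, e.g. a lag time beyond
  # the observation window, from which gradients cannot escape)
  starts <- c(list(de$par),
              diverse_members(de$population, de$energies, de$par,
                              ptab$lower[free], ptab$upper[free]),
              list(ptab$initial[free]))
  refined <- NULL
  for (s in starts) {
    cand <- polish_lbfgsb(obj, s, ptab$lower[free], ptab$upper[free])
    if (is.null(refined) || cand$value < refined$value) refined <- cand
  }
  if (refined$value <= de$value) {
    best_free <- refined$par
    best_value <- refined$value
  } else {
    best_free <- de$par
    best_value <- de$value
  }

  best <- stats::setNames(ptab$initial, ptab$parameter)
  best[free] <- best_free
  at_bound <- free & (abs(best - ptab$lower) <= 1e-8 * pmax(1, abs(ptab$lower)) |
                      abs(best - ptab$upper) <= 1e-8 * pmax(1, abs(ptab$upper)))
  if (any(at_bound)) {
    rlang::warn(sprintf("best fit sits on a bound for: %s",
                        paste(ptab$parameter[at_bound], collapse = ", ")),
                class = "exflux_bound_warning")
  }

  fit <- structure(
    list(model = model, dataset = dataset,
         param_table = dplyr::mutate(ptab, optimal = unname(best)),
         params = best, objective_value = best_value,
         n_data = sum(!is.na(obs_matrix(dataset))), n_params = sum(free),
         alpha = alpha, seed = seed,
         diagnostics = list(de = de[c("value", "iterations", "nfev", "converged")],
                            refine = refined[c("value", "convergence", "counts")],
                            sim_failures = env$n_sim_failures,
                            at_bound = ptab$parameter[at_bound]),
         mc = NULL),
    class = "flux_fit")
  if (mc_iterations > 0) fit <- mc_uncertainty(fit, n_iter = mc_iterations)
  fit
}

# Iterated bounded quasi-Newton refinement. Restarting L-BFGS-B with the
# parameter scale (`parscale`) re-estimated from the current point matters:
# parameters span several orders of magnitude (initial biomass ~1e-2,
# substrate pools ~1e1), and optim's finite-difference steps are taken on
# the parscale-scaled axes, so a single unscaled pass stalls in the narrow
# curved valleys typical of exponential-growth objectives. Passes repeat
# until the objective stops improving.
polish_lbfgsb <- function(obj, start, lower, upper, passes = 6L) {
  capped <- function(p) min(obj(p), 1e100)  # L-BFGS-B cannot digest Inf
  best <- list(par = start, value = capped(start), convergence = NA_integer_,
               counts = c(0L, 0L))
  for (k in seq_len(passes)) {
    res <- tryCatch(
      stats::optim(best$par, capped, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e7,
                                  parscale = pmax(abs(best$par), 1e-6),
                                  ndeps = rep(1e-5, length(start)))),
      error = function(e) NULL
    )
    if (is.null(res) || res$value > best$value) break
    gain <- best$value - res$value
    prev <- best$value
    best <- res[c("par", "value", "convergence", "counts")]
    if (gain <= 1e-12 * max(1, abs(prev))) break
  }
  best
}

# pick up to `k` finite-energy population members well separated (in
# bound-scaled coordinates) from the best point and from each other
diverse_members <- function(pop, energies, best, lower, upper, k = 2L,
                            min_dist = 0.1) {
  span <- pmax(upper - lower, 1e-12)
  scaled <- sweep(pop, 2L, span, `/`)
  picked <- list(sweep(matrix(best, 1L), 2L, span, `/`)[1L, ])
  out <- list()
  for (i in order(energies)) {
    if (!is.finite(energies[i])) break
    cand <- scaled[i, ]
    if (all(vapply(picked, function(p) sqrt(sum((cand - p)^2)), 0) > min_dist)) {
      picked <- c(picked, list(cand))
      out <- c(out, list(pop[i, ]))
      if (length(out) >= k) break
    }
  }
  out
}

resolve_parameters <- function(model, metabolites, overrides) {
  ptab <- model_parameters(model, metabolites)
  ptab$initial <- ptab$default
  ptab$fixed <- FALSE
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), ptab$parameter)
    if (length(unknown)) {
      rlang::abort(sprintf("unknown parameter(s) for model '%s': %s",
                           model$name, paste(unknown, collapse = ", ")),
                   class = "exflux_input_error")
    }
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      i <- match(nm, ptab$parameter)
      if (!is.null(ov$lower)) ptab$lower[i] <- ov$lower
      if (!is.null(ov$upper)) ptab$upper[i] <- ov$upper
      if (!is.null(ov$initial)) ptab$initial[i] <- ov$initial
      if (!is.null(ov$fixed)) ptab$fixed[i] <- isTRUE(ov$fixed)
    }
  }
  bad <- !ptab$fixed & (ptab$initial < ptab$lower | ptab$initial > ptab$upper)
  if (any(bad)) {
    rlang::abort(sprintf("initial values outside bounds for: %s",
                         paste(ptab$parameter[bad], collapse = ", ")),
                 class = "exflux_input_error")
  }
  ptab[c("parameter", "initial", "lower", "upper", "fixed")]
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> model '", x$model$name, "', experiment '", x$dataset$experiment,
      "'\n", sep = "")
  cat(sprintf("  objective %.6g over %d observations, %d free parameter(s)\n",
              x$objective_value, x$n_data, x$n_params))
  print(tidy(x))
  invisible(x)
}

#' Simulate the fitted trajectory
#'
#' Evaluates the fitted model at `times` (defaults to a dense 200-point grid
#' spanning the observed interval).
#'
#' @param fit A `flux_fit`.
#' @param times Optional evaluation times.
#' @return Tibble with `time`, `X` and metabolite columns.
#' @export
fitted_trajectory <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  if (is.null(times)) {
    rng <- range(fit$dataset$data$time)
    times <- seq(rng[1], rng[2], length.out = 200L)
  }
  simulate_model(fit$model, fit$params, times, fit$dataset$metabolites)
}
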