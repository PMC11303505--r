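#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter estimates of a fitted growth model
#'
#' One row per model parameter: the point estimate, the bounds used in the
#' search, and — when a Monte-Carlo analysis was run — the bootstrap mean,
#' standard deviation and 95% confidence interval. Fixed parameters carry
#' `fixed = TRUE` and empty Monte-Carlo columns.
#'
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `lower`, `upper`,
#'   `fixed`, `mc_mean`, `mc_sd`, `ci_lower`, `ci_upper`.
#' @exportS3Method generics::tidy
tidy.flux_fit <- function(x, ...) {
  out <- tibble::tibble(
    parameter = x$param_table$parameter,
    estimate = unname(x$params),
    lower = x$param_table$lower,
    upper = x$param_table$upper,
    fixed = x$param_table$fixed,
    mc_mean = NA_real_, mc_sd = NA_real_,
    ci_lower = NA_real_, ci_upper = NA_real_
  )
  if (!is.null(x$mc)) {
    i <- match(x$mc$ci$parameter, out$parameter)
    out$mc_mean[i] <- x$mc$ci$mean
    out$mc_sd[i] <- x$mc$ci$sd
    out$ci_lower[i] <- x$mc$ci$ci_lower
    out$ci_upper[i] <- x$mc$ci$ci_upper
  }
  out
}

#' One-row summary of a fitted growth model
#'
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, experiment, objective value, data
#'   and parameter counts, chi-squared test results and information criteria
#'   (see [stat_report()]).
#' @exportS3Method generics::glance
glance.flux_fit <- function(x, ...) {
  rep <- stat_report(x)
  dplyr::bind_cols(
    rep[c("model", "experiment")],
    tibble::tibble(objective_value = x$objective_value),
    rep[setdiff(names(rep), c("model", "experiment"))]
  )
}
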