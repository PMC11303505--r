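#' Chi-squared goodness-of-fit test
#'
#' With known measurement standard deviations, the optimal weighted
#' objective \eqn{c} is asymptotically \eqn{\chi^2}-distributed with
#' `n_data - n_params` degrees of freedom when the model is adequate. The
#' upper-tail p-value `1 - F(c; dof)` is compared with `alpha`: the fit is
#' `"accepted"` when `p >= alpha` (no evidence of misfit), `"rejected"`
#' otherwise.
#'
#' @param objective_value Optimal weighted sum of squared errors.
#' @param n_data Number of non-missing observations used in the fit.
#' @param n_params Number of free parameters.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `chi2_stat`, `dof`, `p_value`, `verdict`, `alpha`.
#' @export
gof_test <- function(objective_value, n_data, n_params, alpha = 0.05) {
  dof <- n_data - n_params
  if (dof <= 0) {
    rlang::abort(sprintf("chi-squared test needs n_data > n_params (dof = %d); add observations or fix parameters",
                         dof),
                 class = "exflux_stat_error")
  }
  stopifnot(objective_value >= 0, alpha > 0, alpha < 1)
  p <- stats::pchisq(objective_value, df = dof, lower.tail = FALSE)
  tibble::tibble(chi2_stat = objective_value, dof = as.integer(dof), p_value = p,
                 verdict = if (p >= alpha) "accepted" else "rejected",
                 alpha = alpha)
}

#' Akaike information criteria for a weighted least-squares fit
#'
#' Least-squares form on the weighted objective:
#' `AIC = n * log(c / n) + 2k` and the small-sample correction
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)`. The additive constant dropped
#' from the likelihood is shared by all models fitted to the same data, so
#' differences (and rankings) are unaffected. A perfect fit (`c = 0`) yields
#' `AIC = -Inf` with a warning; `AICc` is reported as `NA` when
#' `n <= k + 1`.
#'
#' @inheritParams gof_test
#' @return One-row tibble with `aic` and `aicc`.
#' @export
aic_scores <- function(objective_value, n_data, n_params) {
  stopifnot(objective_value >= 0, n_data >= 1, n_params >= 0)
  if (objective_value == 0) {
    rlang::warn("objective is exactly 0; AIC is -Inf", class = "exflux_aic_warning")
    aic <- -Inf
  } else {
    aic <- n_data * log(objective_value / n_data) + 2 * n_params
  }
  aicc <- if (n_data > n_params + 1) {
    aic + 2 * n_params * (n_params + 1) / (n_data - n_params - 1)
  } else {
    NA_real_
  }
  tibble::tibble(aic = aic, aicc = aicc)
}

#' Statistical report for one fitted model
#'
#' Combines the chi-squared goodness-of-fit test and the information
#' criteria into a single row, rankable across candidate models fitted to
#' the same dataset with [rank_models()].
#'
#' @param fit A `flux_fit`.
#' @param alpha Significance level (defaults to the one stored in the fit).
#' @return One-row tibble: `model`, `experiment`, `n_data`, `n_params`,
#'   `chi2_stat`, `dof`, `p_value`, `verdict`, `alpha`, `aic`, `aicc`.
#' @export
stat_report <- function(fit, alpha = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  alpha <- alpha %||% fit$alpha
  dplyr::bind_cols(
    tibble::tibble(model = fit$model$name, experiment = fit$dataset$experiment,
                   n_data = fit$n_data, n_params = fit$n_params),
    gof_test(fit$objective_value, fit$n_data, fit$n_params, alpha),
    aic_scores(fit$objective_value, fit$n_data, fit$n_params)
  )
}

#' Rank candidate models by information criteria
#'
#' Sorts statistical reports of models fitted to the same dataset by AICc
#' (falling back to AIC where AICc is undefined), ascending, with ties
#' broken by model name. Each row carries `delta_aic`, the difference of
#' the ranking criterion to the best model; rows with `delta_aic < 2` are
#' flagged `similar_support`, following the usual reading that such models
#' are statistically indistinguishable in quality.
#'
#' @param reports A data frame of [stat_report()] rows (two or more), or a
#'   list of `flux_fit`/report objects.
#' @return The report tibble sorted by rank, with `delta_aic` and
#'   `similar_support` columns appended.
#' @export
rank_models <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- dplyr::bind_rows(lapply(reports, function(r) {
      if (inherits(r, "flux_fit")) stat_report(r) else tibble::as_tibble(r)
    }))
  }
  reports <- tibble::as_tibble(reports)
  if (nrow(reports) < 2L) {
    rlang::abort("model ranking needs at least 2 reports", class = "exflux_stat_error")
  }
  if (dplyr::n_distinct(reports$n_data) != 1L) {
    rlang::abort("reports compare different datasets (mismatched n_data); rank models fitted to the same data only",
                 class = "exflux_stat_error")
  }
  key <- ifelse(is.na(reports$aicc), reports$aic, reports$aicc)
  ord <- order(key, reports$model)
  out <- reports[ord, , drop = FALSE]
  key <- key[ord]
  out$delta_aic <- key - key[1L]
  out$similar_support <- out$delta_aic < 2
  out
}
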