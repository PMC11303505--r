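#' Fitted-versus-measured panels for a flux fit
#'
#' One panel per measured variable (biomass and each metabolite):
#' observations as points with ±1σ error bars and the fitted trajectory as
#' a dense curve (200 evaluation points spanning the observed interval).
#'
#' @param object A `flux_fit`.
#' @param n_curve Number of evaluation points for the fitted curve.
#' @param ... Unused.
#' @return A `ggplot` object, faceted by variable.
#' @exportS3Method ggplot2::autoplot
autoplot.flux_fit <- function(object, n_curve = 200L, ...) {
  d <- object$dataset$data
  vars <- c("X", object$dataset$metabolites)
  obs_long <- tidyr::pivot_longer(d, dplyr::all_of(vars),
                                  names_to = "variable", values_to = "observed") |>
    dplyr::filter(!is.na(.data$observed)) |>
    dplyr::mutate(sd = unname(object$dataset$sds[.data$variable]))
  rng <- range(d$time)
  curve_long <- fitted_trajectory(object, seq(rng[1], rng[2], length.out = n_curve)) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable",
                        values_to = "fitted")
  ggplot2::ggplot() +
    ggplot2::geom_line(data = curve_long,
                       ggplot2::aes(x = .data$time, y = .data$fitted),
                       colour = "#2166ac") +
    ggplot2::geom_errorbar(data = obs_long,
                           ggplot2::aes(x = .data$time,
                                        ymin = .data$observed - .data$sd,
                                        ymax = .data$observed + .data$sd),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point(data = obs_long,
                        ggplot2::aes(x = .data$time, y = .data$observed),
                        size = 1.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration",
                  title = sprintf("model '%s', experiment '%s'",
                                  object$model$name, object$dataset$experiment)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write fitted-vs-measured plots to pdf and svg
#'
#' Renders [autoplot.flux_fit()] to `<path_prefix>.pdf` and
#' `<path_prefix>.svg`.
#'
#' @param fit A `flux_fit`.
#' @param path_prefix Output path without extension.
#' @return Invisibly, the two file paths written.
#' @export
write_plots <- function(fit, path_prefix) {
  p <- autoplot(fit)
  paths <- paste0(path_prefix, c(".pdf", ".svg"))
  grDevices::pdf(paths[1], width = 8, height = 4.5)
  print(p)
  grDevices::dev.off()
  grDevices::svg(paths[2], width = 8, height = 4.5)
  print(p)
  grDevices::dev.off()
  invisible(paths)
}
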