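#' Tidy a fitted transfer model
#'
#' One row per fitted parameter with the estimate, linearized standard
#' error and symmetric 95% confidence limits.
#'
#' @param x A [fit_transfer()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
#' @method tidy transfer_fit
tidy.transfer_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    conf.low = unname(x$estimates - x$ci95),
    conf.high = unname(x$estimates + x$ci95)
  )
}

#' Glance at a fitted transfer model
#'
#' @param x A [fit_transfer()] result.
#' @param ... Unused.
#' @return A one-row tibble: `scenario`, `objective`, `n_obs`,
#'   `n_excluded`, `n_restarts`, `converged`.
#' @export
#' @method glance transfer_fit
glance.transfer_fit <- function(x, ...) {
  tibble(
    scenario = x$scenario$name,
    objective = x$objective,
    n_obs = x$n_obs,
    n_excluded = x$n_excluded,
    n_restarts = x$n_restarts,
    converged = identical(x$convergence, 0L)
  )
}

#' Plot a fitted transfer model against its data
#'
#' Observed reservoir concentrations (points) with the fitted model's
#' predictions (lines), faceted by experiment.
#'
#' @param object A [fit_transfer()] result.
#' @param data The observed data the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot transfer_fit
autoplot.transfer_fit <- function(object, data, ...) {
  times <- seq(0, max(data$time_min), length.out = 61)
  grid <- tidyr::expand_grid(
    dosing_side = unique(data$dosing_side),
    sampled_reservoir = c("maternal", "fetal"),
    time_min = times
  )
  grid$experiment_id <- "fit"
  grid$conc_mg_per_L <- 1 # placeholder; predictions come from the model
  grid <- predict_observed(grid, object$system, object$initial_concentration)
  ids <- dplyr::distinct(data, .data$experiment_id, .data$dosing_side)
  curves <- dplyr::inner_join(ids, dplyr::select(grid, -"experiment_id"),
                              by = "dosing_side", relationship = "many-to-many")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$conc_mg_per_L,
                                     colour = .data$sampled_reservoir),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$pred_mg_per_L,
                                    colour = .data$sampled_reservoir)) +
    ggplot2::facet_wrap(~experiment_id) +
    ggplot2::labs(x = "Time [min]", y = "Concentration [mg/L]",
                  colour = "Reservoir") +
    ggplot2::theme_minimal()
}
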