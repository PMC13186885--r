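## ggplot2 displays for datasets, fits, study tables and grids.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   facet_wrap facet_grid labs theme_minimal scale_fill_gradient2
#'   scale_fill_viridis_c geom_vline
#' @export
ggplot2::autoplot

#' Plot a timecourse dataset
#'
#' Observed responses against the recorded protocol times; if the hidden
#' true times are present they are shown alongside for comparison.
#'
#' @param object A timecourse tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timecourse
#' @export
autoplot.timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("protocol_time", "true_time"),
                              names_to = "time_kind", values_to = "time")
  long <- dplyr::filter(long, !is.na(.data$time))
  ggplot(long, aes(.data$time, .data$response,
                   colour = .data$time_kind,
                   group = interaction(.data$subject_id, .data$time_kind))) +
    geom_point(alpha = 0.7) +
    labs(x = "time", y = "response", colour = NULL,
         title = attr(object, "timerr_design")) +
    theme_minimal()
}

#' Plot a least-squares fit
#'
#' Data used in the fit with the fitted model curve overlaid.
#'
#' @param object A `timerr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timerr_fit
#' @export
autoplot.timerr_fit <- function(object, ...) {
  tgrid <- seq(min(object$data$t), max(object$data$t), length.out = 200)
  pars <- c(as.list(object$theta_hat), as.list(object$fixed))
  curve <- tibble::tibble(
    t = tgrid, y = evaluate_model(pars, tgrid, model_id = object$model_id)
  )
  ggplot(object$data, aes(.data$t, .data$y)) +
    geom_point(alpha = 0.6) +
    geom_line(data = curve, colour = "firebrick") +
    labs(x = paste(object$time, "time"), y = "response",
         title = paste(object$model_id, "fit")) +
    theme_minimal()
}

#' Plot a SIMEX trajectory
#'
#' Mean estimates against the inflation factor `zeta` with the corrected
#' extrapolation at `zeta = -1`.
#'
#' @param object A `timerr_simex`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timerr_simex
#' @export
autoplot.timerr_simex <- function(object, ...) {
  corr <- tibble::tibble(term = names(object$estimates),
                         estimate = unname(object$estimates), zeta = -1)
  ggplot(object$trajectory, aes(.data$zeta, .data$estimate)) +
    geom_point() + geom_line() +
    geom_point(data = corr, colour = "firebrick", shape = 17, size = 2) +
    geom_vline(xintercept = 0, linetype = 3) +
    facet_wrap(~term, scales = "free_y") +
    labs(x = expression(zeta), y = "mean estimate",
         title = paste("SIMEX extrapolation (", object$extrapolant, ")")) +
    theme_minimal()
}

#' Density plot of replicated estimates
#'
#' Kernel densities of a parameter's estimates from a [run_study()] table,
#' split by scenario and by whether the true or the observed times were
#' fitted.
#'
#' @param study_table Output of [run_study()].
#' @param parameter Parameter name.
#' @param truth Optional true value drawn as a vertical reference line.
#' @param what `"estimate"` or `"ci_width"`.
#' @return A ggplot.
#' @export
plot_estimate_density <- function(study_table, parameter, truth = NULL,
                                  what = c("estimate", "ci_width")) {
  what <- match.arg(what)
  dens <- estimate_density(study_table, parameter, what)
  p <- ggplot(dens, aes(.data$x, .data$density, colour = .data$data)) +
    geom_line() +
    facet_wrap(~scenario, scales = "free") +
    labs(x = parameter, y = "density", colour = "fitted data") +
    theme_minimal()
  if (!is.null(truth) && what == "estimate") {
    p <- p + geom_vline(xintercept = truth, linetype = 2)
  }
  p
}

#' Heatmap of a grid summary
#'
#' Tile plot of one metric of a [bias_variance_grid()] table over its two
#' error axes, faceted by parameter.
#'
#' @param grid_table Output of [bias_variance_grid()].
#' @param metric Column to colour by (e.g. `"bias"`, `"variance"`,
#'   `"map_abs_error"`, `"ci_distance"`).
#' @return A ggplot.
#' @export
plot_grid_heatmap <- function(grid_table, metric = "bias") {
  axes <- intersect(c("sigma_U", "sigma_eps", "Delta", "sigma_Y"),
                    names(grid_table))
  ggplot(grid_table, aes(.data[[axes[1]]], .data[[axes[2]]],
                         fill = .data[[metric]])) +
    geom_tile() +
    facet_wrap(~parameter) +
    scale_fill_viridis_c() +
    labs(fill = metric) +
    theme_minimal()
}
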