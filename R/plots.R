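# ggplot2 visualizations for fits, cost curves and sweeps.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_step geom_tile geom_vline facet_wrap facet_grid labs
#'   scale_y_log10 scale_fill_viridis_c theme_minimal
NULL

#' Plot a fitted model against its data
#'
#' Fitted mRNA trajectories per gene with the one-standard-deviation
#' multiplicative-error band and the observations.
#'
#' @param object a `grn_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grn_fit <- function(object, ...) {
  if (object$failed) abort("cannot plot a failed fit.")
  band <- uncertainty_band(object)
  ggplot(band, aes(x = .data$time_h)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper,
                    fill = .data$gene), alpha = 0.25) +
    geom_line(aes(y = .data$value, colour = .data$gene)) +
    geom_point(data = object$data,
               aes(y = .data$value, colour = .data$gene), size = 1) +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "time (h post-synchronization)", y = "scaled expression",
         colour = "gene", fill = "gene") +
    theme_minimal()
}

#' Plot a cost curve over ranked model structures
#'
#' @param object a [cost_curve()] (optionally with acceptability labels).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grn_cost_curve <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$rank, y = .data$nll))
  if ("acceptable" %in% names(object)) {
    p <- p + geom_point(aes(colour = .data$acceptable), size = 0.6) +
      geom_vline(xintercept = sum(object$acceptable) + 0.5,
                 linetype = "dashed")
  } else {
    p <- p + geom_point(size = 0.6)
  }
  p + labs(x = "model rank", y = "negative log-likelihood") +
    theme_minimal()
}

#' Heat map of a misspecification sweep
#'
#' One panel per candidate structure, cells colored by best negative
#' log-likelihood across the sampling-rate by noise-level grid; the
#' approximate experimental regime is outlined.
#'
#' @param sweep a [misspecification_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot(sweep, aes(x = factor(.data$sampling_count),
                    y = factor(.data$cv), fill = .data$nll)) +
    geom_tile() +
    geom_tile(data = dplyr::filter(sweep, .data$experimental_regime),
              fill = NA, colour = "yellow", linewidth = 1) +
    facet_wrap(~candidate) +
    scale_fill_viridis_c() +
    labs(x = "number of time points", y = "noise level (cv)",
         fill = "nll") +
    theme_minimal()
}
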