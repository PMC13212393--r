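# ggplot2 visualisations and broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object an `mrc_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mrc_roc
#' @export
autoplot.mrc_roc <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves of a classifier report
#'
#' @param object an `mrc_classifier_report` from [cohort_report()].
#' @param ... unused.
#' @return a ggplot overlaying the per-model ROC curves.
#' @method autoplot mrc_classifier_report
#' @export
autoplot.mrc_classifier_report <- function(object, ...) {
  scores <- attr(object, "scores")
  y <- attr(object, "labels")
  cv <- purrr::imap_dfr(as.list(scores), function(s, nm) {
    roc <- auc_roc(s, y)
    dplyr::mutate(roc$curve,
                  model = sprintf("%s (%.3f)", nm, roc$auc))
  })
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one fitted parameter map
#'
#' @param maps an `mrc_maps` tibble.
#' @param metric column to display (e.g. `"v_in"`, `"rho"`, `"ADC_PGSE"`).
#' @param slice z-slice to show.
#' @return a ggplot raster of the selected slice.
#' @export
plot_parameter_map <- function(maps, metric = "v_in", slice = 1) {
  stopifnot(metric %in% names(maps))
  tb <- tibble::as_tibble(maps)
  tb <- tb[tb$z == slice, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[metric]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot signal decay curves by sequence
#'
#' @param signals tibble with columns `sequence`, `b_s_mm2`, `signal`
#'   (e.g. from [simulate_signals()]).
#' @return a ggplot of log-signal vs b.
#' @export
plot_signal_decay <- function(signals) {
  ggplot2::ggplot(signals, ggplot2::aes(x = .data$b_s_mm2, y = .data$signal,
                                        colour = .data$sequence)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(b ~ (s/mm^2)), y = "Normalized signal") +
    ggplot2::theme_minimal()
}

#' Tidy a parameter-map table
#'
#' Long format: one row per (voxel, metric).
#'
#' @param x an `mrc_maps`.
#' @param ... unused.
#' @return a tibble `voxel`, `x`, `y`, `z`, `metric`, `value`.
#' @method tidy mrc_maps
#' @export
tidy.mrc_maps <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tidyr::pivot_longer(tb, -c("voxel", "x", "y", "z", "converged", "at_bound"),
                      names_to = "metric", values_to = "value")
}

#' One-line fit summary of a parameter map
#'
#' @param x an `mrc_maps`.
#' @param ... unused.
#' @return tibble with voxel counts, convergence and boundary fractions,
#'   and median residual norm.
#' @method glance mrc_maps
#' @export
glance.mrc_maps <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(n_voxels = nrow(tb),
                 convergence_fraction = mean(tb$converged %in% TRUE),
                 at_bound_fraction = mean(tb$at_bound %in% TRUE),
                 median_objective = stats::median(tb$objective, na.rm = TRUE),
                 model = attr(x, "model"))
}

#' Tidy a logistic fit
#'
#' @param x an `mrc_logistic`.
#' @param ... unused.
#' @return coefficient table (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`).
#' @method tidy mrc_logistic
#' @export
tidy.mrc_logistic <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' One-line summary of a logistic fit
#'
#' @param x an `mrc_logistic`.
#' @param ... unused.
#' @return tibble with AUC of the in-sample probabilities, deviance, AIC,
#'   and a separation flag.
#' @method glance mrc_logistic
#' @export
glance.mrc_logistic <- function(x, ...) {
  y <- x$model$y
  tibble::tibble(auc = auc_roc(x$probabilities, y)$auc,
                 deviance = stats::deviance(x$model),
                 aic = stats::AIC(x$model),
                 separation = x$separation)
}

#' Tidy a classifier report
#'
#' @param x an `mrc_classifier_report`.
#' @param ... unused.
#' @return the report as a plain tibble.
#' @method tidy mrc_classifier_report
#' @export
tidy.mrc_classifier_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "scores") <- NULL
  attr(out, "labels") <- NULL
  out
}
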