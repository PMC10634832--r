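# broom-style tidiers for the package's fitted objects.

#' Tidy an RL model fit
#'
#' @param x An `rl_fit` from [fit_agent_mle()].
#' @param ... Unused.
#' @return A tibble with one row per free parameter.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("learning_rate", "inverse_temperature", "decay"),
    estimate = c(x$params$learning_rate, x$params$inverse_temperature,
                 x$params$decay)
  )
}

#' One-row summary of an RL model fit
#'
#' @inheritParams tidy.rl_fit
#' @return A one-row tibble: log-likelihood, number of trials and restarts,
#'   convergence and boundary flags.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    n_trials = x$n_trials,
    n_restarts = x$n_restarts,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Tidy an EM learning-curve estimate
#'
#' @param x An `em_learning` from [em_learning_curve()].
#' @param ... Unused.
#' @return The per-trial tibble (trial, outcome, p_mode, p_lower95,
#'   p_upper95).
#' @export
tidy.em_learning <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("trial", "outcome", "p_mode",
                                 "p_lower95", "p_upper95")])
}

#' One-row summary of an EM learning-curve estimate
#'
#' @inheritParams tidy.em_learning
#' @return A one-row tibble: `learning_trial`, `process_variance`,
#'   `em_iterations`, `n_trials`.
#' @export
glance.em_learning <- function(x, ...) {
  tibble::tibble(
    learning_trial = attr(x, "learning_trial"),
    process_variance = attr(x, "process_variance"),
    em_iterations = attr(x, "em_iterations"),
    n_trials = nrow(x)
  )
}

#' Plot an EM learning curve
#'
#' Smoothed probability correct with its 95% confidence band, the observed
#' outcomes, chance level, and the statistically defined learning trial.
#'
#' @param object An `em_learning` estimate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.em_learning <- function(object, ...) {
  df <- tidy(object)
  lt <- attr(object, "learning_trial")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p_lower95, ymax = .data$p_upper95),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_mode),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$outcome), shape = 124) +
    ggplot2::geom_hline(yintercept = attr(object, "chance"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Trial in block", y = "P(correct)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.na(lt)) {
    p <- p + ggplot2::geom_vline(xintercept = lt, colour = "firebrick",
                                 linetype = "dotted")
  }
  p
}

#' Plot averaged learning curves per condition
#'
#' @param curves Named list of [average_learning_curve()] tibbles (names =
#'   condition labels), or a single such tibble.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  if (is.data.frame(curves)) {
    curves <- list(all = curves)
  }
  df <- dplyr::bind_rows(curves, .id = "condition")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial,
                                   y = .data$prop_correct,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$prop_correct - .data$se,
                   ymax = .data$prop_correct + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Trial in block", y = "Proportion correct") +
    ggplot2::theme_minimal()
}

#' Plot the condition-comparison grid
#'
#' Tile plot of the difference in mean correlation (condition A minus B)
#' per (area, variable, sign class); tested cells with permutation
#' p < alpha are outlined.
#'
#' @param comparison Output of [population_compare()].
#' @param alpha Significance level for outlining.
#' @return A ggplot object.
#' @export
plot_comparison_grid <- function(comparison, alpha = 0.05) {
  df <- dplyr::mutate(
    comparison,
    sig = .data$tested & !is.na(.data$permutation_p) &
      .data$permutation_p < alpha
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sign_class,
                                   y = .data$variable,
                                   fill = .data$delta)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$sig),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey95") +
    ggplot2::facet_wrap(~area) +
    ggplot2::labs(x = "Sign class", y = NULL, fill = "Δ mean r") +
    ggplot2::theme_minimal()
}

#' Plot waveform classes in metric space
#'
#' @param classified Output of [classify_units()].
#' @return A ggplot object.
#' @export
plot_waveform_classes <- function(classified) {
  cols <- scheme_metric_cols(classified$scheme[1])
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data[[cols[1]]], y = .data[[cols[2]]],
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(NS = "firebrick",
                                            BS = "steelblue")) +
    ggplot2::labs(colour = "Class") +
    ggplot2::theme_minimal()
}
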