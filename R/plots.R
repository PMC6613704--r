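#' Plot a ROC curve
#'
#' @param object A `cfa_roc` tibble from [roc_curve()] or the mean curve of
#'   a [run_experiment()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cfa_roc <- function(object, ...) {
  has_band <- "mean_tpr" %in% names(object)
  y <- if (has_band) "mean_tpr" else "tpr"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data[[y]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
  if (has_band && "sd_tpr" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_tpr - .data$sd_tpr),
                   ymax = pmin(1, .data$mean_tpr + .data$sd_tpr)),
      alpha = 0.2, fill = "#2c7fb8")
  }
  p
}

#' Plot contact-survival histograms
#'
#' Log-scale frequency of contacts surviving at least `tau` iterations, one
#' line per agent — the standard frustration diagnostic (educated
#' populations decay approximately exponentially; untrained ones show heavy
#' tails).
#'
#' @param object A `cfa_survival` tibble from [survival_histogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cfa_survival <- function(object, ...) {
  d <- dplyr::filter(object, .data$count > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = .data$count,
                                  group = interaction(.data$type, .data$agent),
                                  colour = .data$type)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau~"(iterations)"),
                  y = expression("contacts surviving" >= tau)) +
    ggplot2::theme_minimal()
}

#' Plot a training trace
#'
#' The adaptive pairing-duration threshold `tau_n` against total iterations;
#' nonincreasing by construction.
#'
#' @param object A `cfa_trained`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cfa_trained <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iterations, y = .data$tau_n)) +
    ggplot2::geom_step(colour = "#d95f02") +
    ggplot2::labs(x = "iterations", y = expression(tau[n])) +
    ggplot2::theme_minimal()
}

#' Plot the education-theory comparison
#'
#' Expected absorption times from the fully incorrect state against `n`,
#' per strategy (closed form as lines, simulation as points when present).
#'
#' @param object A `cfa_markov` tibble from [markov_table()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cfa_markov <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n,
                                            y = .data$K_closed_form,
                                            colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "top positions to educate, n",
                  y = "expected iterations to full correction") +
    ggplot2::theme_minimal()
  if (any(!is.na(object$K_simulated))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$K_simulated))
  }
  p
}
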