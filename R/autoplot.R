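# ggplot2 autoplot methods for the package's result types.

#' Plot a scattering profile
#'
#' @param object A `saxs_profile`.
#' @param log_y Use a log10 intensity axis.
#' @param ... Unused.
#' @export
autoplot.saxs_profile <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)")
  if (is_experimental(object))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$I - .data$sigma, ymax = .data$I + .data$sigma),
      linewidth = 0.2, alpha = 0.3)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::theme_minimal()
}

#' Plot a SAXS fit (data, fitted curve and residuals)
#'
#' @param object A `saxs_fit`.
#' @param ... Unused.
#' @export
autoplot.saxs_fit <- function(object, ...) {
  df <- object$profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$I_exp), size = 0.6,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$I_fit), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  subtitle = sprintf("chi2 = %.3f", object$chi2)) +
    ggplot2::theme_minimal()
}

#' Plot a dimensionless Kratky curve
#'
#' Dashed guidelines mark the compact-globule reference point
#' \eqn{(\sqrt{3}, 3/e)}.
#'
#' @param object A `kratky_curve`.
#' @param ... Unused.
#' @export
autoplot.kratky_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(qR[g]),
                  y = expression((qR[g])^2 ~ I(q) / I(0))) +
    ggplot2::theme_minimal()
}

#' Plot a pair-distance distribution
#'
#' @param object A `pr_dist`.
#' @param ... Unused.
#' @export
autoplot.pr_dist <- function(object, ...) {
  ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_col(width = diff(object$pr$r[1:2]) * 0.9) +
    ggplot2::labs(x = "r (Å)", y = "P(r)") +
    ggplot2::theme_minimal()
}

#' Plot the chi2 trajectory of an ion subset search
#'
#' @param object An `ion_selection`.
#' @param ... Unused.
#' @export
autoplot.ion_selection <- function(object, ...) {
  df <- tidy.ion_selection(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$chi2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Mg ions added", y = expression(chi^2)) +
    ggplot2::theme_minimal()
}

#' Plot chi2 against state count for a multistate scan
#'
#' @param object A `state_scan`.
#' @param ... Unused.
#' @export
autoplot.state_scan <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n_states, y = .data$chi2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of states", y = expression(chi^2)) +
    ggplot2::theme_minimal()
}

#' Plot the training-loss history of a site classifier
#'
#' @param object An `ion_classifier`.
#' @param ... Unused.
#' @export
autoplot.ion_classifier <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$history),
                       loss = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}
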