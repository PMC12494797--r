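# ggplot2 autoplot methods for the package's result types.

#' @export
autoplot.saxs_curve <- function(object, log = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)")
  if (log) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.saxs_guinier <- function(object, which = c("fit", "residuals"),
                                  ...) {
  which <- match.arg(which)
  if (which == "fit") {
    ggplot2::ggplot(object$data, ggplot2::aes(x = .data$q2)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$lnI), size = 0.8) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
      ggplot2::labs(x = expression(q^2 ~ (ring(A)^-2)), y = "ln I(q)",
                    title = sprintf("Guinier fit: Rg = %.1f A", object$Rg))
  } else {
    ggplot2::ggplot(object$data,
                    ggplot2::aes(x = .data$q2, y = .data$resid_std)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = expression(q^2 ~ (ring(A)^-2)),
                    y = "standardised residual")
  }
}

#' @export
autoplot.saxs_kratky <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = sqrt(3), y = 3 / exp(1), shape = 3,
                      colour = "red3", size = 3) +
    ggplot2::labs(x = expression(R[g] * q),
                  y = expression((R[g] * q)^2 * I(q) / I(0)),
                  title = "Dimensionless Kratky plot")
}

#' @export
autoplot.saxs_pr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p - .data$p_se,
                                      ymax = .data$p + .data$p_se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (A)", y = "p(r)",
                  title = sprintf("p(r): Dmax = %.0f A", object$Dmax))
}

#' @export
autoplot.saxs_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$data, c("I", "I_model"),
                            names_to = "series", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$intensity,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q)",
                  title = sprintf("chi2 = %.2f", object$chi2_red))
}

#' @export
autoplot.saxs_rb <- function(object, ...) autoplot(object$fit, ...)

#' @export
autoplot.saxs_mapscan <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$threshold, y = .data$chi2_red)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_threshold, linetype = 2,
                        colour = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "map threshold", y = "reduced chi2")
}
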