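#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a learning curve on log-log axes
#'
#' Per-repeat test RMSEs, their means, and (when available) the fitted
#' power-law decay.
#'
#' @param object A `learning_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_curve <- function(object, ...) {
  tb <- object$table
  means <- dplyr::summarise(dplyr::group_by(tb, .data$Ntrain),
                            rmse = mean(.data$RMSE_test), .groups = "drop")
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$Ntrain, y = .data$RMSE_test)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$rmse), linewidth = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "training set size", y = "test RMSE")
  if (!is.null(object$fit) && isTRUE(object$fit$b_identifiable)) {
    fit <- object$fit
    grid <- tibble::tibble(
      Ntrain = exp(seq(log(min(tb$Ntrain)), log(max(tb$Ntrain)), length.out = 100))
    )
    grid$rmse <- fit$eps_a + fit$a / grid$Ntrain^fit$b
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$rmse),
                                linetype = "dashed", color = "red")
  }
  p
}

#' Plot an absorption cross section
#'
#' @param object A spectrum tibble from [cross_section()].
#' @param ... Unused.
#' @return A ggplot object (cross section in Angstrom^2/molecule vs photon
#'   energy in eV).
#' @export
autoplot.nea_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$E_eV, y = .data$sigma)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "photon energy (eV)",
                  y = expression(sigma ~ (ring(A)^2 / molecule)))
}

#' Plot predicted vs reference values from a model evaluation
#'
#' @param object The list returned by [evaluate_model()], or an
#'   `error_report` is not plottable on its own — pass `y_hat` and `y`.
#' @param y_hat,y Estimated and reference value vectors.
#' @return A ggplot scatter with the identity line.
#' @export
plot_parity <- function(y_hat, y, object = NULL) {
  tb <- tibble::tibble(y = y, y_hat = y_hat)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$y, y = .data$y_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "reference", y = "estimated")
}
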