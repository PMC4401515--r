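#' Bland-Altman plot for one pair of measurement series
#'
#' @param x,y Paired numeric vectors; differences are `x - y`.
#' @param title Optional plot title.
#' @return A ggplot: per-pair mean versus difference, with the bias line and
#'   the 95\% limits of agreement.
#' @export
plot_bland_altman <- function(x, y, title = NULL) {
  summ <- bland_altman(x, y)
  df <- tibble::tibble(avg = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = summ$bias, linetype = "solid") +
    ggplot2::geom_hline(
      yintercept = c(summ$loa_low, summ$loa_high), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean of pair (%)", y = "Difference (%)",
      title = title,
      subtitle = sprintf(
        "bias %.2f, limits of agreement [%.2f, %.2f]",
        summ$bias, summ$loa_low, summ$loa_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a multi-method agreement report
#'
#' @param object A `ki67_report`.
#' @param type `"ranking"` (weighted sums with the qualification threshold)
#'   or `"kappa"` (Fleiss' kappa per method and cut-off).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ki67_report <- function(object, type = c("ranking", "kappa"), ...) {
  type <- match.arg(type)
  if (type == "ranking") {
    df <- object$scores
    ggplot2::ggplot(
      df,
      ggplot2::aes(
        x = stats::reorder(.data$method, -.data$weighted),
        y = .data$weighted, fill = .data$qualified
      )
    ) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = object$config$rho0, linetype = "dashed") +
      ggplot2::labs(
        x = "Assessment method", y = "Weighted reliability score",
        fill = "Qualified"
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- object$kappa
    ggplot2::ggplot(
      df,
      ggplot2::aes(
        x = .data$method, y = .data$kappa,
        fill = factor(.data$cutoff)
      )
    ) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(
        x = "Assessment method", y = "Fleiss' kappa", fill = "Cut-off (%)"
      ) +
      ggplot2::theme_minimal()
  }
}
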