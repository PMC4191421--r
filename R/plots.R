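#' Plot methods
#'
#' `autoplot()` methods for the package's result types: population
#' histograms as percent bar charts, difference histograms with the positive
#' lobe highlighted, and Langmuir fits as titration points with error bars
#' and the fitted isotherm curve.
#'
#' @param object A `fret_histogram`, `fret_difference` or `langmuir_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-gquadfret
NULL

#' @rdname autoplot-gquadfret
#' @export
autoplot.fret_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_left + df$bin_right) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$percent)) +
    ggplot2::geom_col(width = df$bin_right[1] - df$bin_left[1],
                      fill = "grey35") +
    ggplot2::labs(x = expression(E[FRET]), y = "Population (%)") +
    ggplot2::theme_classic()
}

#' @rdname autoplot-gquadfret
#' @export
autoplot.fret_difference <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_left + df$bin_right) / 2
  df$sign <- ifelse(df$delta_percent >= 0, "gain", "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$delta_percent,
                                   fill = .data$sign)) +
    ggplot2::geom_col(width = df$bin_right[1] - df$bin_left[1],
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(gain = "firebrick",
                                          loss = "steelblue")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = expression(E[FRET]), y = expression(Delta * " (%)")) +
    ggplot2::theme_classic()
}

#' @rdname autoplot-gquadfret
#' @export
autoplot.langmuir_fit <- function(object, ...) {
  d <- object$data
  xmax <- max(d$x)
  curve <- tibble::tibble(x = seq(0, xmax, length.out = 200))
  curve$y <- langmuir(curve$x, object$params$alpha, object$params$k_eq)
  ylab <- if (object$response == "folding") {
    "Relative folded population (%)"
  } else {
    "Unfolded population (%)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$y_err,
                                        ymax = .data$y + .data$y_err),
                           width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = sprintf("Effector concentration (%s)",
                              object$params$units),
                  y = ylab) +
    ggplot2::theme_classic()
}

#' Overlay FRET histograms from several conditions
#'
#' @param histograms Named list of `fret_histogram` objects.
#' @return A ggplot object with one outline per condition.
#' @export
plot_histogram_overlay <- function(histograms) {
  stopifnot(is.list(histograms), length(histograms) >= 1)
  df <- purrr::imap(histograms, function(h, nm) {
    d <- tibble::as_tibble(h)
    d$mid <- (d$bin_left + d$bin_right) / 2
    d$label <- nm
    d
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$percent,
                                   colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(E[FRET]), y = "Population (%)",
                  colour = NULL) +
    ggplot2::theme_classic()
}
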