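#' Plot a persistence diagram
#'
#' Birth/death scatter with the diagonal; essential features of an uncapped
#' diagram are drawn at the top of the plotting range with a distinct shape.
#'
#' @param object A [persistence_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot persistence_diagram
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  df <- tibble::tibble(dimension = factor(object$dimension),
                       birth = object$birth, death = object$death)
  finite_max <- suppressWarnings(max(df$death[is.finite(df$death)], df$birth, 0))
  top <- if (is.finite(attr(object, "maxscale"))) {
    max(attr(object, "maxscale"), finite_max)
  } else {
    finite_max * 1.05 + 1e-9
  }
  df$essential <- !is.finite(df$death)
  df$death[df$essential] <- top
  ggplot2::ggplot(df, ggplot2::aes(x = .data$birth, y = .data$death,
                                   colour = .data$dimension,
                                   shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::coord_equal(xlim = c(0, top), ylim = c(0, top)) +
    ggplot2::labs(x = "birth", y = "death", colour = "dim",
                  title = "Persistence diagram")
}

#' Barcode plot of a persistence diagram
#'
#' One horizontal segment per feature from birth to death (capped features
#' end at the cap). Zero-length bars are dropped from the display.
#'
#' @param diag A [persistence_diagram()].
#' @return A ggplot object.
#' @export
plot_barcode <- function(diag) {
  stopifnot(inherits(diag, "persistence_diagram"))
  df <- tibble::tibble(dimension = factor(diag$dimension),
                       birth = diag$birth, death = diag$death)
  df <- df[df$death > df$birth, , drop = FALSE]
  cap <- attr(diag, "maxscale")
  df$death[!is.finite(df$death)] <- if (is.finite(cap)) cap else max(df$death[is.finite(df$death)], 1)
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  df$bar <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$bar, colour = .data$dimension)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$death,
                                       yend = .data$bar), linewidth = 1) +
    ggplot2::labs(x = "scale", y = NULL, colour = "dim",
                  title = "Persistence barcode") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Bar chart of benchmark accuracies
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phca_benchmark
#' @export
autoplot.phca_benchmark <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "overall accuracy",
                  title = "Cross-validated accuracy by method")
}
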