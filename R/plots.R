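#' Plot an FVA result
#'
#' Flux ranges per reaction as horizontal ranges, ordered by span.
#'
#' @param object An `fva_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fva_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$reaction_id <- stats::reorder(df$reaction_id, df$span)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$reaction_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$vmin, xend = .data$vmax,
                                       yend = .data$reaction_id),
                          linewidth = 1.2, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$vmin), size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(x = .data$vmax), size = 0.8) +
    ggplot2::labs(x = "flux (mmol/g-DW/h)", y = NULL,
                  title = sprintf("Flux variability (gamma = %.2f)",
                                  attr(object, "gamma") %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot flux span ratios
#'
#' Span in condition A against span in condition B on log axes, coloured
#' by class, with the classification thresholds drawn as ratio guide
#' lines.
#'
#' @param object An `fsr_result` (ideally after [classify_fsr()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fsr_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$class != "degenerate", ]
  thr <- attr(object, "thresholds") %||% c(low = 0.8, high = 2)
  eps <- 1e-6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$span_b + eps,
                                   y = .data$span_a + eps,
                                   colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = log10(thr[["low"]]),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = log10(thr[["high"]]),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "span, condition B", y = "span, condition A",
                  colour = NULL, title = "Flux span ratio") +
    ggplot2::theme_minimal()
}

#' Secretion-change heat map
#'
#' The red/white/black-style classification matrix of secretome changes:
#' exchanges by comparison, tiled by change class.
#'
#' @param comparisons Named list of [compare_secretomes()] tables (one
#'   per condition pair), or a single such table.
#' @return A ggplot.
#' @export
plot_secretome_matrix <- function(comparisons) {
  if (is.data.frame(comparisons)) {
    comparisons <- list(comparison = comparisons)
  }
  df <- dplyr::bind_rows(comparisons, .id = "comparison")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                   y = .data$exchange_id,
                                   fill = .data$change)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(increased = "firebrick",
                                          same = "white",
                                          decreased = "black")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "secretion") +
    ggplot2::theme_minimal()
}
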