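# ggplot2 views of the main result types.

#' Heatmap of a repeat conservation map
#'
#' Repeats on the vertical axis (repeat 1 on top, matching the extracellular
#' orientation), solvent-exposed positions across; fill is the regional
#' (default) or raw conservation score.
#'
#' @param object An [rcm_map()] result.
#' @param statistic `"regional"` or `"raw"`.
#' @param highlight Optional tibble with `rep`, `pos` cells to outline
#'   (e.g. mapped pocket residues).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_map <- function(object, statistic = c("regional", "raw"),
                             highlight = NULL, ...) {
  statistic <- match.arg(statistic)
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$rep,
                                        fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(df$rep)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = statistic) +
    ggplot2::labs(x = "solvent-exposed position", y = "LRR repeat") +
    ggplot2::theme_minimal()
  if (!is.null(highlight) && nrow(highlight))
    p <- p + ggplot2::geom_tile(data = highlight,
                                ggplot2::aes(x = .data$pos, y = .data$rep),
                                inherit.aes = FALSE, fill = NA,
                                colour = "red", linewidth = 0.8)
  p
}

#' Null distribution of an enrichment test
#'
#' Histogram of permuted mean conservation with the observed value marked.
#'
#' @param object An [enrichment_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "null mean regional conservation", y = "permutations",
                  subtitle = sprintf("observed %.3f, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Information-content profile of a peptide motif
#'
#' Bar height is per-position information content; bars at the motif
#' anchor positions can be highlighted by the caller via `anchors`.
#'
#' @param object A [motif_statistics()] result.
#' @param anchors Positions to highlight (default 5 and 7).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_summary <- function(object, anchors = c(5, 7), ...) {
  df <- tibble(position = seq_along(object$ic), ic = object$ic,
               anchor = seq_along(object$ic) %in% anchors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ic,
                                   fill = .data$anchor)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("grey60", "firebrick")) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(x = "mature peptide position",
                  y = "information content (bits)") +
    ggplot2::theme_minimal()
}
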