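#' Plot a PCA embedding
#'
#' @param object An `embedding_result`.
#' @param dims Two component indices to plot.
#' @param color Optional per-cell factor (named by cell id or in row order).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embedding_result <- function(object, dims = c(1, 2), color = NULL,
                                      ...) {
  df <- tibble::tibble(x = object$pcs[, dims[1]], y = object$pcs[, dims[2]])
  if (!is.null(color)) df$color <- color
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2])) +
    ggplot2::theme_minimal()
  if (is.null(color)) p + ggplot2::geom_point(size = 0.8, alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$color),
                               size = 0.8, alpha = 0.7) +
    ggplot2::labs(color = NULL)
}

#' Plot a diffusion map
#'
#' DC1-DC2 scatter, optionally colored (e.g. by cluster or genotype) and
#' with the fate-bias selection highlighted when present.
#'
#' @param object A `diffusion_result`.
#' @param color Optional per-cell factor in cell order.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_result <- function(object, color = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$DC1, .data$DC2)) +
    ggplot2::theme_minimal()
  if (!is.null(color)) {
    df$color <- color
    p <- p + ggplot2::geom_point(data = df,
                                 ggplot2::aes(color = .data$color),
                                 size = 0.8, alpha = 0.7) +
      ggplot2::labs(color = NULL)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, alpha = 0.7)
  }
  if ("biased" %in% names(df)) {
    p <- p + ggplot2::geom_point(data = df[df$biased, ],
                                 shape = 21, size = 1.6, stroke = 0.6,
                                 color = "black", fill = NA)
  }
  p
}

#' Conservation heatmap of the specificity index
#'
#' Family-by-dataset tile plot of the cell-type specificity index, rows
#' grouped by conservation class; unannotated families are blank.
#'
#' @param result A `conservation_result` from [build_program_table()].
#' @return A ggplot.
#' @export
plot_conservation <- function(result) {
  stopifnot(inherits(result, "conservation_result"))
  long <- result$specificity |>
    tidyr::pivot_longer(-"family", names_to = "dataset",
                        values_to = "specificity") |>
    dplyr::left_join(result$records[, c("family", "class")], by = "family")
  long$family <- factor(long$family, levels = rev(result$records$family))
  ggplot2::ggplot(long, ggplot2::aes(.data$dataset, .data$family,
                                     fill = .data$specificity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "% of mRNA\nin target") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Anchor-correlation waterfall
#'
#' Genes ranked by correlation to the anchor, colored by call.
#'
#' @param result A `regionalization_result` from [anchor_correlation()].
#' @param top_n Show only the `top_n` most-correlated genes each way
#'   (default all called genes plus the strongest null genes).
#' @return A ggplot.
#' @export
plot_regionalization <- function(result, top_n = 25L) {
  df <- result |>
    dplyr::arrange(dplyr::desc(.data$r)) |>
    dplyr::filter(dplyr::row_number() <= top_n |
                    dplyr::row_number() > dplyr::n() - top_n)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(.data$gene, .data$r,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1,
                                                       size = 6)) +
    ggplot2::labs(x = NULL, y = "correlation with anchor", fill = NULL)
}

#' Hue trace over time with confidence band
#'
#' @param ts Output of [hue_timeseries()].
#' @return A ggplot.
#' @export
plot_hue_timeseries <- function(ts) {
  ggplot2::ggplot(ts, ggplot2::aes(.data$time, .data$mean_hue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "time (min)", y = "shifted hue (degrees)")
}
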