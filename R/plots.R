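# ggplot2 views of the main result types.

#' Volcano plot of a moderated t fit
#'
#' @param object A `de_fit`.
#' @param lfc,alpha Cuts used to color significant genes (defaults 0.5,
#'   0.05, the DEG thresholds).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_fit <- function(object, lfc = 0.5, alpha = 0.05, ...) {
  tbl <- object$table
  tbl$status <- dplyr::case_when(
    tbl$p < alpha & tbl$log2fc > lfc ~ "up",
    tbl$p < alpha & tbl$log2fc < -lfc ~ "down",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p), colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(
      x = "log2 fold change (case - control)", y = "-log10 p",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Lollipop chart of top aggregated items
#'
#' Shows the `n` best-scoring items of an RRA aggregation; dot size encodes
#' rank, colour encodes the fold-change direction when available.
#'
#' @param object An `rra_result` from [rra_aggregate()] (or the
#'   [select_robust()] table).
#' @param n Number of items to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rra_result <- function(object, n = 20, ...) {
  tbl <- as_tibble(object)
  tbl <- head(tbl[order(tbl$score, tbl$item), ], n)
  tbl$item <- factor(tbl$item, levels = rev(tbl$item))
  tbl$direction <- if ("direction" %in% names(tbl)) {
    tbl$direction
  } else if (all(is.na(tbl$mean_lfc))) {
    "n/a"
  } else {
    ifelse(tbl$mean_lfc >= 0, "up", "down")
  }
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = -log10(.data$score), y = .data$item, colour = .data$direction
  )) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = -log10(.data$score), yend = .data$item),
      linewidth = 0.4, colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$score))) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", `n/a` = "grey40")
    ) +
    ggplot2::guides(size = "none") +
    ggplot2::labs(x = "-log10 RRA score", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tripartite layout plot of a ceRNA network
#'
#' circRNAs, miRNAs and mRNAs are drawn in three columns with their
#' circ-mi and mi-mRNA edges.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, ...) {
  nodes <- object$nodes
  layers <- c(circRNA = 1, miRNA = 2, mRNA = 3)
  nodes$x <- layers[nodes$class]
  nodes$y <- stats::ave(seq_len(nrow(nodes)), nodes$class, FUN = function(i) {
    seq_along(i) / (length(i) + 1)
  })
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$node)]
  edges$y <- nodes$y[match(edges$from, nodes$node)]
  edges$xend <- nodes$x[match(edges$to, nodes$node)]
  edges$yend <- nodes$y[match(edges$to, nodes$node)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey75", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class, colour = .data$direction),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 2.4, vjust = -1
    ) +
    ggplot2::scale_x_continuous(
      breaks = unname(layers), labels = names(layers), limits = c(0.5, 3.5)
    ) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9"), na.value = "grey40"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
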