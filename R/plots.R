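#' Kaplan-Meier plot of a prognostic result
#'
#' Step curves of the low- and high-risk groups, annotated with the
#' log-rank p-value and the high-versus-low hazard ratio.
#'
#' @param object a `prognostic_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.prognostic_result <- function(object, ...) {
  lab <- sprintf(
    "HR = %.2f, log-rank p = %.2g%s",
    object$hazard_ratio$hr, object$logrank$p,
    if (object$split$optimistic_p) " (optimized cutpoint)" else ""
  )
  ggplot2::ggplot(
    object$km,
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Survival probability", colour = "Risk group",
      subtitle = lab
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a module correlation matrix
#'
#' Lower triangle: response-state correlations; upper triangle:
#' nonresponse-state correlations; unit diagonal.
#'
#' @param object a `module_cor_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.module_cor_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- as_tibble(as.table(m), .name_repair = ~ c("gene_row", "gene_col", "r"))
  df$gene_row <- factor(df$gene_row, levels = rev(rownames(m)))
  df$gene_col <- factor(df$gene_col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_col, .data$gene_row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "r",
      subtitle = "lower: response, upper: nonresponse"
    ) +
    ggplot2::theme_minimal()
}

#' Degree versus betweenness scatter of network nodes
#'
#' @param metrics tibble from [node_metrics()], optionally with an
#'   `is_hub` column to highlight the selected module.
#' @return a ggplot object.
#' @export
plot_node_metrics <- function(metrics) {
  p <- ggplot2::ggplot(
    metrics,
    ggplot2::aes(x = .data$degree, y = .data$betweenness)
  ) +
    ggplot2::labs(x = "Degree", y = "Betweenness") +
    ggplot2::theme_minimal()
  if ("is_hub" %in% names(metrics)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$is_hub))
  } else {
    p + ggplot2::geom_point()
  }
}
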