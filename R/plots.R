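#' Plot a proportion table
#'
#' Pooled tables become stacked composition bars per group; unpooled tables
#' become per-sample points grouped by condition, one facet per cluster,
#' annotated with the adjusted p-value when test results are attached. The
#' plot is a pure function of the table: nothing is recomputed.
#'
#' @param tab A [cell_proportions()] table.
#' @return A ggplot object.
#' @export
plot_proportions <- function(tab) {
  stopifnot(inherits(tab, "proportion_table"))
  df <- as.data.frame(tab)
  if (identical(attr(tab, "mode"), "pooled")) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                          y = .data$proportion,
                                          fill = .data$cluster)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::labs(x = "group", y = paste0("proportion of ",
                                            attr(tab, "reference")),
                    title = "Pooled cell proportions")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                          y = .data$proportion,
                                          colour = .data$group)) +
      ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1,
                                                              seed = 1)) +
      ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                            width = 0.4, linewidth = 0.3,
                            colour = "black") +
      ggplot2::facet_wrap(~cluster, scales = "free_y") +
      ggplot2::labs(x = "group", y = paste0("proportion of ",
                                            attr(tab, "reference")),
                    title = "Per-sample cell proportions") +
      ggplot2::guides(colour = "none")
    test <- attr(tab, "test")
    if (!is.null(test)) {
      ann <- data.frame(cluster = test$cluster,
                        label = sprintf("adj. p = %.3g", test$p_adj))
      p <- p + ggplot2::geom_text(
        data = ann,
        ggplot2::aes(label = .data$label),
        x = 1.5, y = Inf, vjust = 1.5, inherit.aes = FALSE, size = 3)
    }
  }
  p
}

#' Scatter plot of an embedding
#'
#' @param pi A `pi_obj`.
#' @param reduction Reduction to plot (first two columns used).
#' @param color_by `"leaf"`/`"current"`/integer depth (label coloring via
#'   [resolve_labels()]) or a gene id (expression coloring).
#' @return A ggplot object.
#' @export
plot_embedding <- function(pi, reduction = NULL, color_by = "leaf") {
  stopifnot(inherits(pi, "pi_obj"))
  if (is.null(reduction)) reduction <- names(pi$reductions)[1]
  mat <- pi$reductions[[reduction]]
  if (is.null(mat)) stop("reduction '", reduction, "' not found",
                         call. = FALSE)
  df <- data.frame(x = mat[, 1], y = mat[, 2])
  if (identical(color_by, "leaf") || identical(color_by, "current") ||
      is.numeric(color_by)) {
    df$colour <- level_labels(pi, color_by)
    legend <- "label"
    scale <- NULL
  } else if (color_by %in% rownames(pi$expression)) {
    df$colour <- as.numeric(pi$expression[color_by, ])
    legend <- color_by
    scale <- ggplot2::scale_colour_viridis_c()
  } else {
    stop("`color_by` must be a label level or a gene id", call. = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$colour)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = paste0(reduction, " 1"), y = paste0(reduction, " 2"),
                  colour = legend)
  if (!is.null(scale)) p <- p + scale
  p
}

#' Before/after silhouette heatmap
#'
#' Tile view of per-cluster mean silhouette widths on the two embeddings of
#' an [compare_embeddings()] result.
#'
#' @param cmp An `embedding_comparison`.
#' @return A ggplot object.
#' @export
plot_silhouette <- function(cmp) {
  stopifnot(inherits(cmp, "embedding_comparison"))
  d <- cmp$deltas
  long <- rbind(
    data.frame(cluster = d$cluster, embedding = cmp$before$embedding,
               mean_sil = d$before),
    data.frame(cluster = d$cluster, embedding = cmp$after$embedding,
               mean_sil = d$after)
  )
  long$embedding <- factor(long$embedding,
                           levels = c(cmp$before$embedding,
                                      cmp$after$embedding))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$embedding, y = .data$cluster,
                                     fill = .data$mean_sil)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
                                                    .data$mean_sil)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean\nsilhouette")
}
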