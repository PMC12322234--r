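# ggplot2 views of the main result types; display only, never part of the
# computation path.

#' @export
#' @method autoplot metabo_kdiag
autoplot.metabo_kdiag <- function(object, ...) {
  tbl <- object$table
  long <- tidyr::pivot_longer(
    dplyr::select(tbl, "k", "wss", "gap", "silhouette"),
    cols = c("wss", "gap", "silhouette"),
    names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("wss", "gap", "silhouette"),
                        c("Within-cluster SS", "Gap statistic",
                          "Mean silhouette"))
  chosen <- object$chosen$combined
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = chosen, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = sprintf("Cluster-number diagnostics (combined k = %d)",
                                  chosen)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot metabo_clusters
autoplot.metabo_clusters <- function(object, ...) {
  ord <- order(object$labels$cluster, object$labels$sample_id)
  ids <- object$labels$sample_id[ord]
  C <- object$coassociation[ids, ids]
  long <- tidyr::expand_grid(row = ids, col = ids)
  long$coassociation <- as.vector(t(C))
  long$row <- factor(long$row, rev(ids))
  long$col <- factor(long$col, ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$coassociation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus co-association (k = %d, %d reps)",
                                  object$k, object$n_reps)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
#' @method autoplot metabo_contrast
autoplot.metabo_contrast <- function(object, ...) {
  cl <- attr(object, "clusters")
  df <- as_tibble(tidy(object))
  df$neglog_q <- -log10(pmax(df$q, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = .data$neglog_q,
                                   colour = .data$reject)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_star")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = sprintf("mean log10 ratio difference (cluster %s - %s)",
                              cl[["a"]], cl[["b"]]),
                  y = "-log10 q", colour = "rejected") +
    ggplot2::theme_minimal()
}

#' Heatmap of scaled pathway ratio features
#'
#' Samples are ordered by cluster (when labels are given) and features by
#' average-linkage hierarchical clustering of the correlation distance
#' between features — a display ordering only, with no effect on any
#' result.
#'
#' @param x A `metabo_ratio` tibble (usually the scaled one).
#' @param labels Optional cluster labels used to order and annotate
#'   samples.
#' @return A ggplot object.
#' @export
plot_ratio_heatmap <- function(x, labels = NULL) {
  vals <- ratio_values(x)
  if (!is.null(labels)) {
    lab <- cluster_labels(labels)
    ids <- names(sort(lab))
    vals <- vals[intersect(ids, rownames(vals)), , drop = FALSE]
  }
  if (ncol(vals) > 2L && nrow(vals) > 2L) {
    fd <- 1 - stats::cor(vals)
    feat_ord <- colnames(vals)[hclust(as.dist(fd), "average")$order]
  } else {
    feat_ord <- colnames(vals)
  }
  long <- tidyr::expand_grid(sample_id = rownames(vals), feature = colnames(vals))
  long$value <- as.vector(t(vals))
  long$sample_id <- factor(long$sample_id, rownames(vals))
  long$feature <- factor(long$feature, feat_ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$feature,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nlog10 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Bar chart of the most differential screen targets
#'
#' @param dt A `metabo_screen_diff` tibble.
#' @param n Targets per database to show (default 20).
#' @return A ggplot object.
#' @export
plot_top_targets <- function(dt, n = 20) {
  top <- top_n_targets(dt, n = n)
  top$target <- stats::reorder(paste(top$target, top$database),
                               -top$differential)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$differential, y = .data$target,
                                    fill = .data$pathways)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~database, scales = "free_y") +
    ggplot2::labs(x = "differential z-score (cluster A - B)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
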