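# Figure writers. All plots have a data-table counterpart written by the
# pipeline, so no analysis result exists only as pixels.

pp_need <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    warning(sprintf("package '%s' not available; skipping plot", pkg))
    return(FALSE)
  }
  TRUE
}

#' Correlation heatmap with significance asterisks
#'
#' Seriation-ordered protein correlation heatmap; cells are annotated with
#' asterisks at the Bonferroni-adjusted 0.05 / 0.01 / 0.001 levels.
#'
#' @param cr a `correlation_result`.
#' @param file PNG path.
#' @return The file path (or NULL if the plotting backend is missing).
#' @export
plot_correlation_heatmap <- function(cr, file) {
  if (!pp_need("pheatmap")) return(NULL)
  ord <- cr$leaf_order
  r <- cr$r[ord, ord]
  p <- cr$p_raw[ord, ord]
  stars <- matrix("", nrow(r), ncol(r))
  scale <- cr$alpha_adjusted / 0.05    # adjusted levels
  stars[!is.na(p) & p < 0.001 * scale] <- "***"
  stars[!is.na(p) & p >= 0.001 * scale & p < 0.01 * scale] <- "**"
  stars[!is.na(p) & p >= 0.01 * scale & p < 0.05 * scale] <- "*"
  diag(stars) <- ""
  grDevices::png(file, width = 900, height = 800, res = 150)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(
    r, cluster_rows = FALSE, cluster_cols = FALSE,
    display_numbers = stars, breaks = seq(-1, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("#2166AC", "#FFFFFF",
                                          "#B2182B"))(100),
    main = if (is.null(cr$condition)) "" else cr$condition)
  file
}

#' Subcluster similarity heatmap
#'
#' @param sim result of [subcluster_similarity()].
#' @param file PNG path.
#' @return The file path (or NULL).
#' @export
plot_subcluster_heatmap <- function(sim, file) {
  if (!pp_need("pheatmap")) return(NULL)
  ord <- sim$leaf_order
  grDevices::png(file, width = 1000, height = 900, res = 150)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(
    sim$r[ord, ord], cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(min(sim$r) - 1e-9, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("#2166AC", "#FFFFFF",
                                          "#B2182B"))(100))
  file
}

#' tSNE scatter colored by cluster, shaped by condition
#'
#' @param embedding n x 2 matrix from [embed_tsne()].
#' @param assignments cluster labels.
#' @param condition condition labels.
#' @param file PNG path.
#' @return The file path (or NULL).
#' @export
plot_tsne_clusters <- function(embedding, assignments, condition, file) {
  if (!pp_need("ggplot2")) return(NULL)
  df <- data.frame(tsne1 = embedding[, 1], tsne2 = embedding[, 2],
                   cluster = factor(assignments),
                   condition = factor(condition))
  p <- ggplot2::ggplot(df, ggplot2::aes(
        x = tsne1, y = tsne2, color = cluster, shape = condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = seq_len(nlevels(df$condition))) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
  file
}

#' Stacked phenotype band figure
#'
#' One column of 9 color-coded bands per group, using the colors computed
#' by [build_phenotype()].
#'
#' @param bands data.frame of stacked [build_phenotype()] outputs (with a
#'   `label` column).
#' @param file PNG path.
#' @return The file path (or NULL).
#' @export
plot_phenotype_bands <- function(bands, file) {
  if (!pp_need("ggplot2")) return(NULL)
  bands$feature <- factor(bands$feature, levels = rev(feature_names()))
  fills <- bands$color
  fills[is.na(fills)] <- "#CCCCCC"
  bands$fill <- fills
  p <- ggplot2::ggplot(bands, ggplot2::aes(
        x = label, y = feature, fill = fill)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_identity() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
  ggplot2::ggsave(file, p, width = 8, height = 4.5, dpi = 150)
  file
}

utils::globalVariables(c("tsne1", "tsne2", "cluster", "condition",
                         "label", "feature", "fill"))
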