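#' Plot the selected-model matrix
#'
#' Tile plot of SNPs by characteristics, filled by the selected inheritance
#' model (one panel per criterion when both were run).
#'
#' @param object Output of [analyze_selection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot migselect_selection_tbl
#' @export
autoplot.migselect_selection_tbl <- function(object, ...) {
  dat <- as_tibble(object)
  dat$selected <- factor(dat$selected, levels = inheritance_models()$model)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$characteristic, y = .data$snp_id,
                                    fill = .data$selected)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot permutation-corrected significance
#'
#' Heatmap of -log10 of the fully corrected (rank + Sidak) p-values.
#'
#' @param object Output of [permutation_significance()].
#' @param alpha Significance threshold marked with a star (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot migselect_perm
#' @export
autoplot.migselect_perm <- function(object, alpha = 0.05, ...) {
  dat <- as_tibble(object)
  dat$neglog <- -log10(pmax(dat$sidak_p, 1 / (attr(object, "n_permutations") + 1)))
  dat$star <- ifelse(dat$sidak_p < alpha, "*", "")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$characteristic, y = .data$snp_id,
                                    fill = .data$neglog)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 5) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot stratified effect estimates
#'
#' Point-range grid of the with/without (and overall) log-odds per coded
#' allele, one row per SNP, mirroring the effect-matrix report.
#'
#' @param object Output of [estimate_stratified_effects()].
#' @param snp_order Optional SNP ordering (e.g. the cluster leaf order).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot migselect_effects
#' @export
autoplot.migselect_effects <- function(object, snp_order = NULL, ...) {
  dat <- as_tibble(object)
  dat$characteristic[is.na(dat$characteristic)] <- "actmig"
  if (!is.null(snp_order)) {
    dat$snp_id <- factor(dat$snp_id, levels = snp_order)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$beta,
                                    color = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$beta - 1.96 * .data$se,
                                          ymax = .data$beta + 1.96 * .data$se),
                             linewidth = 0.4, fatten = 1.5) +
    ggplot2::facet_grid(snp_id ~ characteristic) +
    ggplot2::labs(x = NULL, y = "log-odds per coded allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot the selectivity dendrogram
#'
#' @param object A `selectivity_clust` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selectivity_clust
#' @export
autoplot.selectivity_clust <- function(object, ...) {
  if (is.null(object$hclust)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::annotate("text", 0, 0, label = object$order[1]))
  }
  hc <- object$hclust
  n <- length(hc$labels)
  # leaf x-positions in plotting order
  xpos <- numeric(n); xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  segs <- list()
  pos_of <- function(idx, k) {
    if (idx < 0) c(xpos[-idx], 0) else c(node_x[idx], node_y[idx])
  }
  for (k in seq_len(nrow(hc$merge))) {
    a <- pos_of(hc$merge[k, 1], k); b <- pos_of(hc$merge[k, 2], k)
    node_x[k] <- mean(c(a[1], b[1]))
    segs[[k]] <- tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], hc$height[k]), yend = c(hc$height[k], hc$height[k],
                                                hc$height[k])
    )
  }
  segs <- dplyr::bind_rows(segs)
  leaves <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "Mahalanobis merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
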