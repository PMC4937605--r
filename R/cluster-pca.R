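# Sample-embedding conventions: hierarchical clustering with complete
# linkage, either on the samples' correlation vectors with 1 - |r| as the
# distance, or directly on log10 expression with Euclidean distance; and PCA
# of the samples after centering and scaling each gene across all samples.

#' Hierarchically cluster samples
#'
#' In `corr_vector` mode (the default), each sample is represented by its
#' vector of correlations with all samples, and the distance between two
#' samples is one minus the absolute Pearson correlation of their vectors
#' (`1 - |r|`); `abs_corr = FALSE` switches to `1 - r`, which keeps strong
#' anticorrelation distant. In `euclidean` mode the Euclidean distance on
#' log10 expression is used directly. Complete linkage in both modes.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param mode `"corr_vector"` or `"euclidean"`.
#' @param abs_corr Use `1 - |r|` (default) rather than `1 - r` in
#'   `corr_vector` mode.
#' @return An [stats::hclust] object over samples.
#' @export
hcluster_samples <- function(log_expr, mode = c("corr_vector", "euclidean"),
                             abs_corr = TRUE) {
  mode <- match.arg(mode)
  y <- expr_values(log_expr)
  if (ncol(y) < 2) abort("need at least 2 samples to cluster")
  if (mode == "corr_vector") {
    r <- sample_correlations(log_expr)   # errors on constant samples
    rr <- cor(r)                         # correlations between corr vectors
    d <- as.dist(1 - if (abs_corr) abs(rr) else rr)
  } else {
    d <- stats::dist(t(y), method = "euclidean")
  }
  hclust(d, method = "complete")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional file; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' PCA of samples in gene space
#'
#' Standard PCA of the samples after centering (and by default scaling) each
#' gene across all samples. Constant genes are dropped with a warning when
#' scaling. The sign of each component is fixed so its largest-magnitude
#' gene loading is positive.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param samples Optional design tibble; when given, organ and species are
#'   attached to the scores for plotting.
#' @param center,scale Per-gene centering/scaling flags (defaults TRUE).
#' @param n_components Number of leading components to keep (default 3,
#'   truncated with a warning if fewer are available).
#' @return A `pca_result` list: `scores` (tibble, one row per sample),
#'   `loadings` (tibble, one row per gene), `var_explained` (fractions).
#' @export
pca_samples <- function(log_expr, samples = NULL, center = TRUE,
                        scale = TRUE, n_components = 3) {
  y <- expr_values(log_expr)
  if (ncol(y) < 2) abort("need at least 2 samples")
  if (scale) {
    s <- apply(y, 1, sd)
    if (any(s == 0)) {
      warn(paste0(sum(s == 0), " constant gene(s) dropped before PCA"))
      y <- y[s > 0, , drop = FALSE]
    }
  }
  x <- t(y)  # samples as observations, genes as variables
  p <- prcomp(x, center = center, scale. = scale)
  k <- min(n_components, ncol(p$x))
  if (k < n_components) {
    warn(paste0("only ", k, " component(s) available; request truncated"))
  }
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(k)) {
    piv <- which.max(abs(p$rotation[, j]))
    if (p$rotation[piv, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(p$x)),
    tibble::as_tibble(p$x[, seq_len(k), drop = FALSE]))
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores, tibble::as_tibble(samples),
                               by = "sample_id")
  }
  loadings <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(p$rotation)),
    tibble::as_tibble(p$rotation[, seq_len(k), drop = FALSE]))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve[seq_len(k)], n_components = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d samples (%d components kept)\n",
              nrow(x$scores), x$n_components))
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 var_explained_total = sum(x$var_explained))
}

#' @export
autoplot.pca_result <- function(object, colour = "organ", shape = "species",
                                ...) {
  sc <- object$scores
  mapping <- ggplot2::aes(x = .data$PC1, y = .data$PC2)
  if (colour %in% names(sc)) {
    mapping <- utils::modifyList(mapping,
                                 ggplot2::aes(colour = .data[[colour]]))
  }
  if (shape %in% names(sc)) {
    mapping <- utils::modifyList(mapping,
                                 ggplot2::aes(shape = .data[[shape]]))
  }
  ggplot2::ggplot(sc, mapping) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Variance-proportion plane of a classified decomposition
#'
#' Scatter of the species-attributable against the organ-attributable
#' variance proportion per gene, coloured by class, with the dominance and
#' explained-variance guide lines.
#'
#' @param classified Output of [classify_genes()].
#' @param thresholds The [classification_thresholds()] used.
#' @return A ggplot object.
#' @export
plot_variance_plane <- function(classified,
                                thresholds = classification_thresholds()) {
  df <- dplyr::filter(classified, !is.na(.data$p_o))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_s, y = .data$p_o,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = thresholds$fold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = 1 / thresholds$fold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = -1, intercept = thresholds$explained_min,
                         linetype = "dotted") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "variance proportion: species",
                  y = "variance proportion: organ") +
    ggplot2::theme_minimal()
}
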