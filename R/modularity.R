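# Newman modularity of thresholded sample-correlation networks. Samples are
# nodes; an edge joins two samples whose Pearson correlation of log10
# expression exceeds a threshold. Modularity with respect to the organ (or
# species) labelling measures how preferentially edges fall within groups
# relative to a degree-preserving random null:
#   Q = (1/2m) * sum_ij [A_ij - k_i k_j / (2m)] * delta(c_i, c_j)
# with zero diagonal (no self-connections).

#' Pearson correlations between samples
#'
#' @param log_expr Wide log10-expression tibble.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_correlations <- function(log_expr) {
  y <- expr_values(log_expr)
  s <- apply(y, 2, sd)
  if (any(s == 0)) {
    abort(paste0("constant sample column(s): ",
                 paste(colnames(y)[s == 0], collapse = ", ")))
  }
  cor(y)
}

#' Build a thresholded sample network
#'
#' Draws an (unweighted, undirected) edge between two distinct samples when
#' their correlation exceeds `threshold` (strictly, by default; set
#' `rule = "ge"` for inclusive). The diagonal is always zero.
#'
#' @param corr Symmetric sample correlation matrix.
#' @param threshold Correlation cutoff.
#' @param rule `"gt"` (default, edge when `corr > threshold`) or `"ge"`.
#' @return A `sample_network` list: `adjacency`, `nodes`, `m` (edge count),
#'   `degrees`, `threshold`.
#' @export
build_network <- function(corr, threshold, rule = c("gt", "ge")) {
  rule <- match.arg(rule)
  corr <- as.matrix(corr)
  if (max(abs(corr - t(corr))) > 1e-12) abort("correlation matrix must be symmetric")
  A <- if (rule == "gt") (corr > threshold) else (corr >= threshold)
  A <- A * 1
  diag(A) <- 0
  structure(list(adjacency = A,
                 nodes = colnames(corr) %||% as.character(seq_len(ncol(corr))),
                 m = sum(A) / 2,
                 degrees = rowSums(A),
                 threshold = threshold),
            class = "sample_network")
}

#' Newman modularity of a sample network for a given grouping
#'
#' Computes `Q = (1/2m) * sum_ij [A_ij - k_i k_j / (2m)] delta(c_i, c_j)`
#' over all ordered node pairs (the zero diagonal contributes only through
#' the null-model term). Isolated nodes stay in the network with degree 0.
#'
#' @param net A [build_network()] result.
#' @param groups Group label per node (organ or species of each sample), in
#'   node order, or a named vector matched by node name.
#' @return Scalar modularity `Q` (at most 1).
#' @export
modularity_q <- function(net, groups) {
  A <- net$adjacency
  n <- nrow(A)
  if (!is.null(names(groups))) groups <- groups[net$nodes]
  if (length(groups) != n || anyNA(groups)) {
    abort("groups must provide one label per network node")
  }
  if (net$m < 1) abort("modularity is undefined for a network with no edges")
  k <- net$degrees
  two_m <- 2 * net$m
  same <- outer(groups, groups, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' Modularity as a function of network density, for organ and species groupings
#'
#' For each target edge count, a correlation threshold is placed between
#' consecutive order statistics of the off-diagonal correlations so that the
#' realized edge count is as close as possible to the target (ties can make
#' some counts unachievable; the nearest achievable count is used and
#' reported). Modularity is evaluated under both the organ and the species
#' labelling.
#'
#' @param corr Sample correlation matrix (named by sample id).
#' @param samples Design tibble giving each sample's organ and species.
#' @param edge_grid Target edge counts; default: 12 roughly even counts from
#'   `n - 1` up to half the possible edges. Modularity is only informative at
#'   sparse-to-moderate density: as the network approaches the complete
#'   graph, every Q collapses to a structure-free value determined solely by
#'   the group sizes.
#' @return A tibble of class `modularity_curve`: `edges_target`, `edges`,
#'   `threshold`, `density`, `q_organ`, `q_species`.
#' @export
modularity_curve <- function(corr, samples, edge_grid = NULL) {
  design <- sample_design(samples)
  corr <- as.matrix(corr)[design$sample_id, design$sample_id]
  n <- ncol(corr)
  max_edges <- n * (n - 1) / 2
  if (is.null(edge_grid)) {
    edge_grid <- unique(round(seq(n - 1, max_edges / 2, length.out = 12)))
  }
  offdiag <- sort(corr[upper.tri(corr)], decreasing = TRUE)
  organ <- setNames(design$organ, design$sample_id)
  species <- setNames(design$species, design$sample_id)

  rows <- purrr::map_dfr(edge_grid, function(target) {
    target <- max(1L, min(as.integer(target), max_edges))
    # candidate thresholds between consecutive sorted correlations
    thr <- if (target >= max_edges) {
      min(offdiag) - 1e-9
    } else {
      (offdiag[target] + offdiag[target + 1]) / 2
    }
    net <- build_network(corr, thr)
    if (net$m != target) {
      # ties: scan nearby order statistics for the closest achievable count
      cand <- unique(c(offdiag - 1e-12, offdiag + 1e-12, min(offdiag) - 1))
      counts <- vapply(cand, function(t) sum(corr[upper.tri(corr)] > t), 0)
      best <- cand[which.min(abs(counts - target))]
      net <- build_network(corr, best)
      thr <- best
    }
    tibble::tibble(
      edges_target = target, edges = net$m, threshold = thr,
      density = net$m / max_edges,
      q_organ = modularity_q(net, organ),
      q_species = modularity_q(net, species))
  })
  class(rows) <- c("modularity_curve", class(rows))
  rows
}

#' @export
autoplot.modularity_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("q_organ", "q_species"),
                              names_to = "grouping", values_to = "Q",
                              names_prefix = "q_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$edges, y = .data$Q,
                                     colour = .data$grouping)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "edges in network", y = "modularity Q",
                  colour = "grouped by") +
    ggplot2::theme_minimal()
}
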