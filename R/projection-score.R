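# Projection-score selection of the genes most informative for PCA: nested
# gene subsets are formed by thresholding per-gene variance (as a ratio to
# the maximum variance); for each subset the fraction of variance captured by
# the first d principal components (alpha) is compared with its mean over
# permuted datasets, and the subset with the largest excess is selected.

#' Per-gene variance across samples
#'
#' @param log_expr Wide log10-expression tibble.
#' @return Tibble `gene_id`, `variance` (sample variance across columns).
#' @export
gene_variances <- function(log_expr) {
  y <- expr_values(log_expr)
  tibble::tibble(gene_id = log_expr$gene_id,
                 variance = apply(y, 1, var))
}

#' Nested gene subsets by variance-ratio thresholds
#'
#' For each ratio `r` in the grid, the subset contains the genes whose
#' variance is at least `r` times the maximum gene variance (inclusive), so
#' higher thresholds give nested, smaller subsets.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param ratio_grid Fractions in (0, 1].
#' @param min_size Subsets smaller than this are dropped with a warning
#'   (default 4, one more than the default number of components).
#' @return Tibble `ratio`, `size`, `genes` (list-column of gene ids).
#' @export
variance_subsets <- function(log_expr, ratio_grid, min_size = 4) {
  if (any(ratio_grid <= 0) || any(ratio_grid > 1)) {
    abort("ratio thresholds must lie in (0, 1]")
  }
  v <- gene_variances(log_expr)
  vmax <- max(v$variance)
  out <- purrr::map_dfr(sort(unique(ratio_grid)), function(r) {
    ids <- v$gene_id[v$variance >= r * vmax]
    tibble::tibble(ratio = r, size = length(ids), genes = list(ids))
  })
  small <- out$size < min_size
  if (any(small)) {
    warn(paste0(sum(small), " threshold(s) dropped: subset smaller than ",
                min_size, " genes"))
    out <- out[!small, , drop = FALSE]
  }
  if (nrow(out) == 0) abort("no variance threshold leaves enough genes")
  out
}

# standardize genes (rows) across samples; constant rows -> error or drop
standardize_genes <- function(y, scale = TRUE) {
  mu <- rowMeans(y)
  y <- y - mu
  if (scale) {
    s <- sqrt(rowSums(y^2) / (ncol(y) - 1))
    if (all(s == 0)) abort("all genes are constant; alpha is undefined")
    y <- y[s > 0, , drop = FALSE] / s[s > 0]
  } else if (all(abs(y) < .Machine$double.eps)) {
    abort("all genes are constant; alpha is undefined")
  }
  y
}

#' Fraction-of-variance statistic for the leading principal components
#'
#' With genes centered (and by default scaled) across samples, alpha is the
#' square root of the fraction of total variance captured by the first `d`
#' principal components: `sqrt(sum of top-d eigenvalues / sum of all
#' eigenvalues)` of the sample covariance. Equals 1 when the data have rank
#' at most `d`.
#'
#' @param log_expr Wide log10-expression tibble (a gene subset).
#' @param d Number of leading components (default 3).
#' @param scale Scale genes to unit variance after centering (default TRUE).
#' @return Scalar alpha in (0, 1].
#' @export
alpha_statistic <- function(log_expr, d = 3, scale = TRUE) {
  if (nrow(log_expr) < 2) abort("alpha needs at least 2 genes")
  if (d < 1) abort("d must be a positive integer")
  y <- standardize_genes(expr_values(log_expr), scale = scale)
  alpha_from_matrix(y, d)
}

# y already standardized genes x samples
alpha_from_matrix <- function(y, d) {
  ev <- svd(y, nu = 0, nv = 0)$d^2
  ev <- ev[ev > max(ev) * 1e-12]
  if (length(ev) <= d) return(1)
  sqrt(sum(ev[seq_len(d)]) / sum(ev))
}

#' Projection score of a gene subset
#'
#' Observed alpha minus its mean over `n_perm` permuted datasets, where each
#' permutation independently shuffles every gene's values across samples
#' (destroying the sample structure while preserving each gene's marginal
#' distribution).
#'
#' @param log_expr Wide log10-expression tibble (all genes).
#' @param genes Gene ids of the subset to score.
#' @param d Number of leading components (default 3).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutations.
#' @param scale Scale genes before the eigendecomposition (default TRUE).
#' @return One-row tibble: `alpha`, `null_alpha_mean`, `null_alpha_sd`,
#'   `score`.
#' @export
compute_projection_score <- function(log_expr, genes, d = 3, n_perm = 100,
                                     seed = 1L, scale = TRUE) {
  sub <- subset_genes(log_expr, genes)
  y <- standardize_genes(expr_values(sub), scale = scale)
  obs <- alpha_from_matrix(y, d)
  local_seed(seed)
  n <- ncol(y)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- t(apply(y, 1, sample, size = n))
    alpha_from_matrix(perm, d)
  }, 0)
  tibble::tibble(alpha = obs, null_alpha_mean = mean(null),
                 null_alpha_sd = sd(null), score = obs - mean(null))
}

#' Default variance-ratio grid
#'
#' 30 logarithmically spaced thresholds from 1e-4 to 1.
#'
#' @return Numeric vector of ratios.
#' @export
default_ratio_grid <- function() 10^seq(-4, 0, length.out = 30)

#' Select the most informative gene subset by projection score
#'
#' Evaluates the projection score for every variance-ratio subset and selects
#' the subset with the highest score (ties resolved toward the larger
#' subset). PCA restricted to the selected genes typically reproduces, with
#' higher contrast, the sample arrangement obtained from all genes.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param ratio_grid Variance-ratio thresholds (default
#'   [default_ratio_grid()]).
#' @param d Number of leading components (default 3).
#' @param n_perm Permutations per subset (default 100).
#' @param seed Integer seed.
#' @param scale Scale genes before the eigendecomposition (default TRUE).
#' @return A `projection_score_result` list: `table` (per-threshold tibble
#'   `ratio`, `size`, `alpha`, `null_alpha_mean`, `score`), `selected_ratio`,
#'   `selected_genes`, `d`, `n_perm`, `seed`.
#' @export
select_informative_genes <- function(log_expr,
                                     ratio_grid = default_ratio_grid(),
                                     d = 3, n_perm = 100, seed = 1L,
                                     scale = TRUE) {
  subsets <- variance_subsets(log_expr, ratio_grid, min_size = d + 1)
  local_seed(seed)
  sub_seeds <- sample.int(2^31 - 1, nrow(subsets))
  scores <- purrr::map2_dfr(subsets$genes, sub_seeds, function(g, s) {
    compute_projection_score(log_expr, g, d = d, n_perm = n_perm, seed = s,
                             scale = scale)
  })
  tab <- dplyr::bind_cols(dplyr::select(subsets, "ratio", "size"), scores)
  best <- which(tab$score == max(tab$score))
  if (length(best) > 1) best <- best[which.max(tab$size[best])]
  structure(list(table = tab,
                 selected_ratio = tab$ratio[best],
                 selected_genes = subsets$genes[[best]],
                 d = d, n_perm = n_perm, seed = seed),
            class = "projection_score_result")
}

#' @export
print.projection_score_result <- function(x, ...) {
  cat("Projection-score gene selection\n")
  cat(sprintf("  %d thresholds evaluated (d = %d, %d permutations)\n",
              nrow(x$table), x$d, x$n_perm))
  cat(sprintf("  selected ratio %.4g -> %d genes (score %.4f)\n",
              x$selected_ratio, length(x$selected_genes),
              max(x$table$score)))
  invisible(x)
}

#' @export
tidy.projection_score_result <- function(x, ...) x$table

#' @export
glance.projection_score_result <- function(x, ...) {
  tibble::tibble(selected_ratio = x$selected_ratio,
                 n_selected = length(x$selected_genes),
                 best_score = max(x$table$score),
                 d = x$d, n_perm = x$n_perm)
}

#' @export
autoplot.projection_score_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$size, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = length(object$selected_genes),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subset size (genes)", y = "projection score") +
    ggplot2::theme_minimal()
}
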