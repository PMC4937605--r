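# Balanced two-factor ANOVA decomposition of per-gene log10 expression:
# SST = SSO + SSS + SSR, where SSO is n_s * sum of squared organ-mean
# deviations from the grand mean, SSS the species analogue, and SSR the
# residual after removing both additive factors. Balancedness makes the
# sequential sums of squares order-invariant, so no model fitting is needed.

#' Decompose one gene's expression grid into organ/species/residual variation
#'
#' @param grid Numeric `n_o x n_s` matrix of log10 expression values for one
#'   gene (rows = organs, columns = species).
#' @return One-row tibble: `sst`, `sso`, `sss`, `ssr` and the variance
#'   proportions `p_o`, `p_s`, `p_r` (NA when `sst` is zero).
#' @export
decompose_gene <- function(grid) {
  grid <- as.matrix(grid)
  if (!all(is.finite(grid))) abort("grid contains non-finite values")
  n_o <- nrow(grid); n_s <- ncol(grid)
  gm <- mean(grid)
  om <- rowMeans(grid)
  sm <- colMeans(grid)
  sst <- sum((grid - gm)^2)
  sso <- n_s * sum((om - gm)^2)
  sss <- n_o * sum((sm - gm)^2)
  ssr <- sum((grid - outer(om, rep(1, n_s)) -
                outer(rep(1, n_o), sm) + gm)^2)
  if (sst > 0) {
    p <- c(sso, sss, ssr) / sst
  } else {
    p <- rep(NA_real_, 3)
  }
  tibble::tibble(sst = sst, sso = sso, sss = sss, ssr = ssr,
                 p_o = p[1], p_s = p[2], p_r = p[3])
}

#' Decompose every gene of a log-expression matrix
#'
#' Vectorized balanced two-factor decomposition over all genes: for each gene
#' the total sum of squares about the grand mean is split into variation
#' across organs, across species, and residual, and each is expressed as a
#' proportion of the total. Genes with zero total variance get NA proportions.
#'
#' @param log_expr Wide log10-expression tibble (see [log_transform()]).
#' @param samples Balanced design tibble (see [sample_design()]).
#' @return Tibble with one row per gene: `gene_id`, `sst`, `sso`, `sss`,
#'   `ssr`, `p_o`, `p_s`, `p_r`.
#' @export
decompose_all <- function(log_expr, samples) {
  design <- sample_design(samples)
  y <- expr_values(log_expr)[, design$sample_id, drop = FALSE]
  if (!all(is.finite(y))) abort("log-expression contains non-finite values")
  organs <- attr(design, "organs"); species <- attr(design, "species")
  n_o <- length(organs); n_s <- length(species)

  Io <- outer(design$organ, organs, "==") / n_s    # samples x organs
  Is <- outer(design$species, species, "==") / n_o # samples x species
  gm <- rowMeans(y)
  om <- y %*% Io   # genes x organs means
  sm <- y %*% Is   # genes x species means
  sst <- rowSums((y - gm)^2)
  sso <- n_s * rowSums((om - gm)^2)
  sss <- n_o * rowSums((sm - gm)^2)
  fit <- om[, match(design$organ, organs), drop = FALSE] +
    sm[, match(design$species, species), drop = FALSE] - gm
  ssr <- rowSums((y - fit)^2)

  sst <- unname(sst); sso <- unname(sso); sss <- unname(sss)
  ssr <- unname(ssr)
  ok <- sst > 0
  prop <- function(ss) ifelse(ok, ss / sst, NA_real_)
  tibble::tibble(gene_id = rownames(y), sst = sst, sso = sso, sss = sss,
                 ssr = ssr, p_o = prop(sso), p_s = prop(sss),
                 p_r = prop(ssr))
}

#' Summarize a decomposition table
#'
#' Mean variance proportions over genes with positive total variance, plus
#' the share of genes whose residual proportion falls below a cutoff.
#'
#' The `mean_p_*` columns average the per-gene proportions (each gene counts
#' equally); the `pooled_p_*` columns are ratios of summed sums of squares
#' (genes weighted by their total variance), the Monte-Carlo estimator of the
#' ratio of expected sums of squares.
#'
#' @param decomp Output of [decompose_all()].
#' @param p_r_cutoff Residual-proportion cutoff for the cumulative summary
#'   (default 0.35).
#' @return One-row tibble: `n_genes`, `n_zero_variance`, `mean_p_o`,
#'   `mean_p_s`, `mean_p_r`, `pooled_p_o`, `pooled_p_s`, `pooled_p_r`,
#'   `frac_p_r_below`.
#' @export
decomposition_summary <- function(decomp, p_r_cutoff = 0.35) {
  ok <- dplyr::filter(decomp, .data$sst > 0)
  tibble::tibble(
    n_genes = nrow(decomp),
    n_zero_variance = nrow(decomp) - nrow(ok),
    mean_p_o = mean(ok$p_o),
    mean_p_s = mean(ok$p_s),
    mean_p_r = mean(ok$p_r),
    pooled_p_o = sum(ok$sso) / sum(ok$sst),
    pooled_p_s = sum(ok$sss) / sum(ok$sst),
    pooled_p_r = sum(ok$ssr) / sum(ok$sst),
    frac_p_r_below = mean(ok$p_r < p_r_cutoff)
  )
}

#' Per-gene expression dynamic range
#'
#' Orders of magnitude between each gene's maximum and minimum linear-scale
#' expression across all samples, after pseudocount addition:
#' `log10(max + pseudocount) - log10(min + pseudocount)`.
#'
#' @param expr Wide linear-scale expression tibble.
#' @param pseudocount Pseudocount (default 0.01).
#' @return Tibble `gene_id`, `dynamic_range`.
#' @export
dynamic_range <- function(expr, pseudocount = 0.01) {
  m <- expr_values(expr)
  if (ncol(m) == 0) abort("expression matrix has no sample columns")
  if (any(m < 0)) abort("linear-scale expression must be non-negative")
  tibble::tibble(
    gene_id = expr$gene_id,
    dynamic_range = unname(log10(apply(m, 1, max) + pseudocount) -
                             log10(apply(m, 1, min) + pseudocount))
  )
}

#' Classification thresholds for gene classes
#'
#' @param dr_min Minimum dynamic range (orders of magnitude) for a gene to
#'   count as unconstrained (default 2).
#' @param explained_min Minimum combined organ+species variance proportion
#'   (default 0.75).
#' @param fold Minimum dominance ratio between the two proportions
#'   (default 2).
#' @param inclusive Whether threshold comparisons are inclusive (`>=`,
#'   default) or strict.
#' @return A list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(dr_min = 2, explained_min = 0.75,
                                      fold = 2, inclusive = TRUE) {
  if (dr_min <= 0 || explained_min <= 0 || fold <= 0) {
    abort("all thresholds must be positive")
  }
  structure(list(dr_min = dr_min, explained_min = explained_min,
                 fold = fold, inclusive = inclusive),
            class = "classification_thresholds")
}

#' Classify genes as TVG, SVG, other unconstrained, or constrained
#'
#' A gene is constrained when its dynamic range is below `dr_min`. Among
#' unconstrained genes whose combined organ+species proportion reaches
#' `explained_min`, a gene is a tissue-variable gene (TVG) when its organ
#' proportion is at least `fold` times its species proportion, and a
#' species-variable gene (SVG) in the mirrored case; remaining unconstrained
#' genes are "other". The pre-intersection dominance masks (threshold rules
#' applied regardless of dynamic range) are returned alongside.
#'
#' @param decomp Output of [decompose_all()].
#' @param dr Output of [dynamic_range()] covering the same genes.
#' @param thresholds A [classification_thresholds()] object.
#' @return `decomp` joined with `dynamic_range`, plus logical columns
#'   `unconstrained`, `dominant_organ`, `dominant_species` and the factor-like
#'   character column `class` in
#'   `c("tvg", "svg", "other_unconstrained", "constrained")`.
#' @export
classify_genes <- function(decomp, dr,
                           thresholds = classification_thresholds()) {
  if (!setequal(decomp$gene_id, dr$gene_id)) {
    abort("decomposition and dynamic-range tables cover different genes")
  }
  ge <- if (thresholds$inclusive) `>=` else `>`
  out <- dplyr::inner_join(decomp, dr, by = "gene_id")
  out <- dplyr::mutate(
    out,
    unconstrained = ge(.data$dynamic_range, thresholds$dr_min),
    explained = !is.na(.data$p_o) &
      ge(.data$p_o + .data$p_s, thresholds$explained_min),
    dominant_organ = .data$explained & ge(.data$p_o, thresholds$fold * .data$p_s),
    dominant_species = .data$explained & ge(.data$p_s, thresholds$fold * .data$p_o),
    class = dplyr::case_when(
      !.data$unconstrained ~ "constrained",
      .data$dominant_organ ~ "tvg",
      .data$dominant_species ~ "svg",
      TRUE ~ "other_unconstrained"
    )
  )
  dplyr::select(out, -"explained")
}

#' Cancel one factor's variance by within-group centering and scaling
#'
#' For `factor = "organ"`, each gene's values within each organ are centered
#' and scaled across species, so a subsequent decomposition attributes zero
#' variation to organ; `factor = "species"` mirrors this, cancelling species
#' variation. Groups with zero standard deviation map to all zeros.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param samples Balanced design tibble.
#' @param factor Which factor's variance to cancel.
#' @return Transformed wide tibble, same shape and ids.
#' @export
remove_factor_variance <- function(log_expr, samples,
                                   factor = c("organ", "species")) {
  factor <- match.arg(factor)
  design <- sample_design(samples)
  y <- expr_values(log_expr)[, design$sample_id, drop = FALSE]
  groups <- if (factor == "organ") design$organ else design$species
  for (g in unique(groups)) {
    cols <- which(groups == g)
    block <- y[, cols, drop = FALSE]
    mu <- rowMeans(block)
    s <- sqrt(rowSums((block - mu)^2) / (length(cols) - 1))
    centered <- block - mu
    scaled <- centered / ifelse(s > 0, s, 1)
    scaled[s == 0, ] <- 0
    y[, cols] <- scaled
  }
  values_to_expr(y, log_expr$gene_id)
}

#' Standardize each sample (column) to zero mean and unit variance
#'
#' @param log_expr Wide log10-expression tibble.
#' @return Standardized wide tibble.
#' @export
standardize_within_sample <- function(log_expr) {
  y <- expr_values(log_expr)
  mu <- colMeans(y)
  s <- apply(y, 2, sd)
  if (any(s == 0)) {
    abort(paste0("constant sample column(s): ",
                 paste(colnames(y)[s == 0], collapse = ", ")))
  }
  values_to_expr(sweep(sweep(y, 2, mu), 2, s, "/"), log_expr$gene_id)
}

#' Two-species variance decompositions against a reference species
#'
#' For each non-reference species, the reference's and that species' samples
#' are taken as a 2-species x n_o design, standardized within each sample,
#' and decomposed gene by gene. Tracks how the organ-attributable share of
#' expression variance decays (and the species share grows) with evolutionary
#' distance from the reference.
#'
#' @param log_expr Wide log10-expression tibble.
#' @param samples Balanced design tibble.
#' @param reference Reference species label.
#' @param exclude_organs Optional organ labels to drop (e.g. `"testis"`).
#' @return Tibble with columns `species`, `gene_id`, `sst`, `sso`, `sss`,
#'   `ssr`, `p_o`, `p_s`, `p_r`.
#' @export
pairwise_species_decomposition <- function(log_expr, samples, reference,
                                           exclude_organs = NULL) {
  design <- sample_design(samples)
  species <- attr(design, "species")
  if (!reference %in% species) {
    abort(paste0("unknown reference species: ", reference))
  }
  keep <- !design$organ %in% exclude_organs
  design <- sample_design(design[keep, , drop = FALSE])
  purrr::map_dfr(setdiff(species, reference), function(sp) {
    sub <- design[design$species %in% c(reference, sp), , drop = FALSE]
    sub_design <- sample_design(sub)
    cols <- c("gene_id", sub_design$sample_id)
    std <- standardize_within_sample(log_expr[, cols])
    dplyr::mutate(decompose_all(std, sub_design), species = sp, .before = 1)
  })
}
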