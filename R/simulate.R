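# Ground-truth simulator: per gene, log10 expression on a balanced organ x
# species grid follows the additive model y_ij = mu + org_i + spc_j + eps_ij.
# Organ effects and residuals are i.i.d. Gaussian; species effects are either
# i.i.d. or Brownian motion along a phylogeny (covariance decaying with
# evolutionary distance), so that pairwise comparisons against a reference
# species reproduce the distance trend seen in real organ panels.

gene_classes <- c("tvg", "svg", "balanced", "constrained")

# set the RNG locally, restoring the caller's state on exit
local_seed <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(seed)
}

#' Default per-class variance ranges for the simulator
#'
#' Ranges (log10 units squared) from which each gene's organ, species and
#' residual variances are drawn uniformly, by intended class. Tissue-variable
#' (tvg) genes get large organ variance and near-zero species variance;
#' species-variable (svg) genes mirror them; balanced genes get comparable
#' organ and species variance; constrained genes get negligible variance in
#' every component, keeping their expected dynamic range well under 2 orders
#' of magnitude.
#'
#' @return Named list of per-class lists with elements `sigma2_o`, `sigma2_s`,
#'   `sigma2_e`, each a length-2 numeric range.
#' @export
default_variance_ranges <- function() {
  list(
    tvg         = list(sigma2_o = c(1, 4),    sigma2_s = c(0, 0.2),
                       sigma2_e = c(0.05, 0.3)),
    svg         = list(sigma2_o = c(0, 0.2),  sigma2_s = c(1, 4),
                       sigma2_e = c(0.05, 0.3)),
    balanced    = list(sigma2_o = c(0.5, 1),  sigma2_s = c(0.5, 1),
                       sigma2_e = c(0.05, 0.3)),
    constrained = list(sigma2_o = c(0, 0.01), sigma2_s = c(0, 0.01),
                       sigma2_e = c(0, 0.01))
  )
}

#' Default class mixture for the simulator
#'
#' Proportions of tissue-variable, species-variable, balanced and constrained
#' genes, loosely mirroring the composition observed in vertebrate organ
#' panels (organ-variable genes several-fold more common than species-variable
#' ones, and a large constrained fraction).
#'
#' @return Named numeric vector over the four classes, summing to 1.
#' @export
default_class_mixture <- function() {
  c(tvg = 0.20, svg = 0.05, balanced = 0.35, constrained = 0.40)
}

#' Draw per-gene simulation parameters from a class mixture
#'
#' Each gene is assigned a class multinomially and its three variance
#' components are drawn uniformly from that class's ranges; the baseline
#' log10 expression `mu` is uniform on `mu_range`.
#'
#' @param n_genes Number of genes.
#' @param class_mixture Named proportions over
#'   `c("tvg", "svg", "balanced", "constrained")`, summing to 1.
#' @param variance_ranges Per-class ranges, see [default_variance_ranges()].
#' @param mu_range Range for the baseline log10 expression (default 0.5–3,
#'   i.e. roughly 3–1000 on the linear scale; one-to-one orthologous
#'   protein-coding genes are expressed at least somewhere, and low expression
#'   in individual organs or species arises through negative effects).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Tibble with columns `gene_id`, `class`, `mu`, `sigma2_o`,
#'   `sigma2_s`, `sigma2_e`.
#' @export
sample_gene_params <- function(n_genes,
                               class_mixture = default_class_mixture(),
                               variance_ranges = default_variance_ranges(),
                               mu_range = c(0.5, 3),
                               seed = 1L) {
  if (n_genes < 1) abort("n_genes must be a positive integer")
  if (is.null(names(class_mixture)) ||
      !setequal(names(class_mixture), gene_classes)) {
    abort("class_mixture must be named over tvg, svg, balanced, constrained")
  }
  class_mixture <- class_mixture[gene_classes]
  if (any(class_mixture < 0) || abs(sum(class_mixture) - 1) > 1e-9) {
    abort("class_mixture proportions must be non-negative and sum to 1")
  }
  for (cl in gene_classes) {
    r <- variance_ranges[[cl]]
    if (is.null(r)) abort(paste0("variance_ranges lacks class ", cl))
    for (comp in c("sigma2_o", "sigma2_s", "sigma2_e")) {
      if (any(r[[comp]] < 0)) abort("variance range bounds must be >= 0")
    }
  }
  local_seed(seed)
  cls <- sample(gene_classes, n_genes, replace = TRUE, prob = class_mixture)
  draw <- function(comp) {
    lo <- vapply(cls, function(cl) variance_ranges[[cl]][[comp]][1], 0)
    hi <- vapply(cls, function(cl) variance_ranges[[cl]][[comp]][2], 0)
    runif(n_genes, lo, hi)
  }
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    class = cls,
    mu = runif(n_genes, mu_range[1], mu_range[2]),
    sigma2_o = draw("sigma2_o"),
    sigma2_s = draw("sigma2_s"),
    sigma2_e = draw("sigma2_e")
  )
}

#' Default vertebrate species tree
#'
#' Ultrametric 7-tip phylogeny (human, chimpanzee, rhesus macaque, mouse,
#' opossum, platypus, chicken) with branch lengths in millions of years from
#' textbook divergence times. Used to give simulated species effects a
#' Brownian-motion covariance structure.
#'
#' @return An `ape::phylo` tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(chicken:320,(platypus:180,(opossum:160,(mouse:90,",
    "(rhesus:29,(chimpanzee:6,human:6):23):61):70):20):140);"))
}

#' Create a balanced organ x species sample table
#'
#' @param organs Character vector of organ labels.
#' @param species Character vector of species labels.
#' @return A validated design tibble (see [sample_design()]) with sample ids
#'   `<species>_<organ>`.
#' @export
make_design <- function(organs = c("brain", "cerebellum", "heart",
                                   "kidney", "liver", "testis"),
                        species = c("human", "chimpanzee", "rhesus", "mouse",
                                    "opossum", "platypus", "chicken")) {
  grid <- tidyr::expand_grid(species = species, organ = organs)
  sample_design(tibble::tibble(
    sample_id = paste(grid$species, grid$organ, sep = "_"),
    species = grid$species, organ = grid$organ))
}

# Brownian-motion correlation among species: tip variance normalized to 1 so
# a gene's species variance multiplies it directly.
bm_correlation <- function(tree, species) {
  tips <- tree$tip.label
  if (!setequal(tips, species)) {
    abort("tree tips do not match the design's species labels")
  }
  C <- ape::vcv(tree)[species, species]
  d <- diag(C)
  if (any(d <= 0)) abort("every tip must have positive root-to-tip depth")
  C / sqrt(tcrossprod(d))
}

#' Simulate a balanced expression matrix with known variance components
#'
#' Per gene, log10 expression on the organ x species grid is
#' `y_ij = mu + org_i + spc_j + eps_ij`, with organ effects i.i.d.
#' `N(0, sigma2_o)`, residuals i.i.d. `N(0, sigma2_e)` and species effects
#' either i.i.d. `N(0, sigma2_s)` (`tree = NULL`) or multivariate normal with
#' a Brownian-motion correlation along `tree`, scaled so each tip's variance
#' is `sigma2_s`. Linear-scale values are emitted as
#' `max(0, 10^y - pseudocount)`, so [log_transform()] recovers `y` exactly
#' wherever `y >= log10(pseudocount)`.
#'
#' @param design Sample design from [make_design()] or [sample_design()].
#' @param params Per-gene parameter tibble from [sample_gene_params()].
#' @param tree Optional `phylo` tree whose tips match the design's species.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param pseudocount Pseudocount used for the linear-scale emission.
#' @param log_scale If `TRUE`, return the log10 values directly (no emission
#'   round-trip); useful for exact parameter-recovery checks.
#' @return List with `expr` (wide tibble; linear scale unless `log_scale`)
#'   and `truth` (per-gene tibble: parameters, realized effect list-columns
#'   `org_effects` / `spc_effects`, and the variance fractions `true_p_o`,
#'   `true_p_s`, `true_p_r` implied by the realized effects). `expr` carries a
#'   `clipped_fraction` attribute: the share of entries clipped at zero.
#' @export
simulate_expression <- function(design, params, tree = NULL, seed = 1L,
                                pseudocount = 0.01, log_scale = FALSE) {
  organs <- attr(design, "organs")
  species <- attr(design, "species")
  if (is.null(organs) || is.null(species)) {
    design <- sample_design(design)
    organs <- attr(design, "organs")
    species <- attr(design, "species")
  }
  n_o <- length(organs); n_s <- length(species); G <- nrow(params)
  local_seed(seed)

  org <- matrix(rnorm(G * n_o), G, n_o) * sqrt(params$sigma2_o)
  z <- matrix(rnorm(G * n_s), G, n_s)
  if (!is.null(tree)) {
    U <- chol(bm_correlation(tree, species))   # t(U) %*% U = corr
    spc <- (z %*% U) * sqrt(params$sigma2_s)
  } else {
    spc <- z * sqrt(params$sigma2_s)
  }
  eps <- matrix(rnorm(G * n_o * n_s), G, n_o * n_s) * sqrt(params$sigma2_e)

  # columns follow the design order: species-major, organ-minor
  o_idx <- match(design$organ, organs)
  s_idx <- match(design$species, species)
  y <- params$mu + org[, o_idx, drop = FALSE] +
    spc[, s_idx, drop = FALSE] + eps
  colnames(y) <- design$sample_id

  msd <- function(m) rowMeans((m - rowMeans(m))^2)
  v_o <- msd(org); v_s <- msd(spc); v_e <- params$sigma2_e
  tot <- v_o + v_s + v_e
  truth <- dplyr::mutate(
    params,
    org_effects = lapply(seq_len(G), function(g) setNames(org[g, ], organs)),
    spc_effects = lapply(seq_len(G), function(g) setNames(spc[g, ], species)),
    true_p_o = ifelse(tot > 0, v_o / tot, NA_real_),
    true_p_s = ifelse(tot > 0, v_s / tot, NA_real_),
    true_p_r = ifelse(tot > 0, v_e / tot, NA_real_)
  )

  if (log_scale) {
    expr <- values_to_expr(y, params$gene_id)
    attr(expr, "clipped_fraction") <- 0
  } else {
    lin <- 10^y - pseudocount
    lin[lin < 0] <- 0
    expr <- values_to_expr(lin, params$gene_id)
    attr(expr, "clipped_fraction") <- mean(y < log10(pseudocount))
  }
  list(expr = expr, truth = truth)
}
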