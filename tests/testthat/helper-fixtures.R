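# Small in-code fixtures shared across test files.

toy_design <- function(organs = c("brain", "liver"),
                       species = c("human", "mouse")) {
  make_design(organs = organs, species = species)
}

# deterministic linear-scale toy matrix on a 2x2 design
toy_expr <- function(design = toy_design(), n_genes = 3, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(10^runif(n_genes * nrow(design), 0, 2),
                n_genes, nrow(design),
                dimnames = list(NULL, design$sample_id))
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes))),
      tibble::as_tibble(m))
  })
}

write_toy_tsvs <- function(expr, design, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  sp <- file.path(dir, "samples.tsv")
  readr::write_tsv(expr, mp)
  readr::write_tsv(tibble::as_tibble(design), sp)
  list(matrix = mp, samples = sp)
}

# simulation with a single-class mixture and the default ranges
single_class_sim <- function(class, n_genes, design = make_design(),
                             tree = NULL, seed = 1, ...) {
  mix <- setNames(as.numeric(names(default_class_mixture()) == class),
                  names(default_class_mixture()))
  params <- sample_gene_params(n_genes, mix, seed = seed)
  simulate_expression(design, params, tree = tree, seed = seed + 1, ...)
}

# modularity by explicit term-by-term enumeration of the definition
modularity_bruteforce <- function(A, groups) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (groups[i] == groups[j]) {
        q <- q + A[i, j] - k[i] * k[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# modularity via the per-community sum: sum_c [m_c/m - (K_c/(2m))^2]
modularity_community_sum <- function(A, groups) {
  m <- sum(A) / 2
  k <- rowSums(A)
  sum(vapply(unique(groups), function(g) {
    idx <- groups == g
    sum(A[idx, idx]) / (2 * m) - (sum(k[idx]) / (2 * m))^2
  }, 0))
}

random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    groups <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    list(A = A, groups = groups)
  })
}
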