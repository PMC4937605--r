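# End-to-end orchestration: log transform -> decomposition -> classification
# -> modularity curve -> projection score -> clustering/PCA, with every stage
# written as TSV and a JSON manifest capturing parameters and seed.

#' Run the full analysis pipeline and write its artifacts
#'
#' Chains the analysis stages on a linear-scale expression matrix with a
#' balanced design and writes one TSV per stage into `out_dir`, plus a JSON
#' manifest (parameters, seed, input checksums, row counts) sufficient to
#' reproduce the run.
#'
#' @param expr Wide linear-scale expression tibble.
#' @param samples Balanced design tibble.
#' @param out_dir Output directory (created if needed).
#' @param pseudocount Pseudocount for the log transform and dynamic range.
#' @param thresholds [classification_thresholds()] for gene classes.
#' @param ratio_grid Variance-ratio grid for the projection score.
#' @param d,n_perm Projection-score components and permutations.
#' @param edge_grid Target edge counts for the modularity curve (NULL for the
#'   default grid).
#' @param reference Reference species for the pairwise decompositions (NULL
#'   to skip).
#' @param seed Integer seed used for all randomized stages.
#' @return Invisibly, a list with all stage results (`decomposition`,
#'   `classified`, `summary`, `modularity`, `projection`, `pca`, `hclust`,
#'   `pairwise`, `manifest`).
#' @export
run_pipeline <- function(expr, samples, out_dir,
                         pseudocount = 0.01,
                         thresholds = classification_thresholds(),
                         ratio_grid = default_ratio_grid(),
                         d = 3, n_perm = 100,
                         edge_grid = NULL, reference = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- sample_design(samples)
  log_expr <- log_transform(expr, pseudocount)

  decomp <- decompose_all(log_expr, design)
  dr <- dynamic_range(expr, pseudocount)
  classified <- classify_genes(decomp, dr, thresholds)
  readr::write_tsv(classified, file.path(out_dir, "decomposition.tsv"))
  summ <- decomposition_summary(decomp)
  readr::write_tsv(summ, file.path(out_dir, "decomposition_summary.tsv"))

  corr <- sample_correlations(log_expr)
  curve <- modularity_curve(corr, design, edge_grid)
  readr::write_tsv(curve, file.path(out_dir, "modularity_curve.tsv"))

  proj <- select_informative_genes(log_expr, ratio_grid, d = d,
                                   n_perm = n_perm, seed = seed)
  readr::write_tsv(proj$table, file.path(out_dir, "projection_score.tsv"))
  writeLines(proj$selected_genes,
             file.path(out_dir, "informative_genes.txt"))

  pca <- pca_samples(log_expr, design, n_components = d)
  readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"))
  hc <- hcluster_samples(log_expr)
  dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))

  pairwise <- NULL
  if (!is.null(reference)) {
    pairwise <- pairwise_species_decomposition(log_expr, design, reference)
    readr::write_tsv(pairwise, file.path(out_dir, "pairwise_species.tsv"))
  }

  manifest <- list(
    seed = seed, pseudocount = pseudocount,
    thresholds = unclass(thresholds),
    projection = list(d = d, n_perm = n_perm, ratio_grid = ratio_grid),
    reference = reference,
    n_genes = nrow(expr), n_samples = nrow(design),
    organs = attr(design, "organs"), species = attr(design, "species"),
    class_counts = as.list(table(classified$class)),
    input_checksum = digest_expr(expr)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(decomposition = decomp, classified = classified,
                 summary = summ, modularity = curve, projection = proj,
                 pca = pca, hclust = hc, pairwise = pairwise,
                 manifest = manifest))
}

# cheap content checksum without extra dependencies: sum of a stable hash of
# the serialized object
digest_expr <- function(expr) {
  raw <- serialize(expr, NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% .Machine$integer.max,
          length(raw))
}
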