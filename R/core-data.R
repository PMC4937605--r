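# Data model: a wide expression tibble (column `gene_id`, one column per
# sample) paired with a sample table (sample_id, species, organ). The sample
# table must describe a complete organ x species grid -- the closed-form
# decomposition only exists for balanced designs.

#' Validate and normalize a sample design table
#'
#' Checks that a sample table describes a complete, balanced organ x species
#' grid (exactly one sample per cell) and returns it ordered species-major,
#' organ-minor. Organ and species levels keep their order of first appearance.
#'
#' @param samples A data frame with columns `sample_id`, `species`, `organ`
#'   (an optional `individual` column is carried through).
#' @return A tibble with the same columns, one row per (species, organ) cell,
#'   ordered species-major. Attributes `organs` and `species` hold the level
#'   orders.
#' @export
sample_design <- function(samples) {
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "species", "organ")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(samples[req])) abort("sample table contains missing values")
  if (anyDuplicated(samples$sample_id) > 0) {
    abort("duplicate sample_id in sample table")
  }
  organs <- unique(samples$organ)
  species <- unique(samples$species)
  if (any(!nzchar(organs)) || any(!nzchar(species))) {
    abort("organ and species labels must be non-empty")
  }
  cells <- tidyr::expand_grid(species = species, organ = organs)
  counts <- dplyr::count(samples, .data$species, .data$organ)
  chk <- dplyr::left_join(cells, counts, by = c("species", "organ"))
  bad <- dplyr::filter(chk, is.na(.data$n) | .data$n != 1L)
  if (nrow(bad) > 0) {
    cell <- paste0("(", bad$species[1], ", ", bad$organ[1], ")")
    abort(paste0("unbalanced design: cell ", cell,
                 ifelse(is.na(bad$n[1]), " has no sample",
                        paste0(" has ", bad$n[1], " samples"))))
  }
  out <- samples[order(match(samples$species, species),
                       match(samples$organ, organs)), , drop = FALSE]
  attr(out, "organs") <- organs
  attr(out, "species") <- species
  out
}

design_dims <- function(design) {
  c(n_o = length(attr(design, "organs") %||% unique(design$organ)),
    n_s = length(attr(design, "species") %||% unique(design$species)))
}

#' Read an expression matrix and its sample table
#'
#' The matrix TSV has a `gene_id` column followed by one column per sample;
#' the sample table TSV has columns `sample_id`, `species`, `organ`
#' (optionally `individual`). The sample table must describe a complete
#' balanced organ x species grid covering exactly the matrix's sample columns.
#'
#' @param matrix_path Path to the expression TSV (linear-scale values, e.g.
#'   cRPKM).
#' @param sample_table_path Path to the sample table TSV.
#' @return A list with elements `expr` (wide tibble, columns ordered
#'   species-major to match the design) and `samples` (validated design
#'   tibble, see [sample_design()]).
#' @export
read_expression_matrix <- function(matrix_path, sample_table_path) {
  samples <- readr::read_tsv(sample_table_path, col_types = readr::cols(
    .default = readr::col_character()))
  design <- sample_design(samples)
  expr <- readr::read_tsv(matrix_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  if (names(expr)[1] != "gene_id") {
    abort("first column of the expression matrix must be 'gene_id'")
  }
  mat_samples <- names(expr)[-1]
  missing <- setdiff(design$sample_id, mat_samples)
  extra <- setdiff(mat_samples, design$sample_id)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "expression matrix columns do not match the sample table",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ",
                                paste(extra, collapse = ", ")) else ""))
  }
  expr <- expr[, c("gene_id", design$sample_id)]
  validate_expr(expr, linear = TRUE)
  list(expr = expr, samples = design)
}

validate_expr <- function(expr, linear = FALSE) {
  if (anyDuplicated(expr$gene_id) > 0) {
    dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
    abort(paste0("duplicate gene id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("non-finite expression value at gene ",
                 expr$gene_id[bad[1, 1]], ", sample ",
                 colnames(vals)[bad[1, 2]]))
  }
  if (linear) {
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      abort(paste0("negative expression value at gene ",
                   expr$gene_id[neg[1, 1]], ", sample ",
                   colnames(vals)[neg[1, 2]]))
    }
  }
  invisible(expr)
}

#' Write an expression matrix to TSV
#'
#' Values are written with full double precision so that a write/read
#' round-trip is bit-identical.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Log10-transform a linear-scale expression matrix
#'
#' Applies `log10(x + pseudocount)` elementwise; all downstream stages
#' (decomposition, correlation networks, PCA) consume this scale.
#'
#' @param expr Wide linear-scale expression tibble.
#' @param pseudocount Positive value added before the log (default 0.01, so a
#'   zero maps to -2).
#' @return A wide tibble of log10 values with attribute `pseudocount`.
#' @export
log_transform <- function(expr, pseudocount = 0.01) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be a single positive number")
  }
  validate_expr(expr, linear = TRUE)
  out <- dplyr::mutate(expr, dplyr::across(-"gene_id",
                                           ~ log10(.x + pseudocount)))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Subset an expression matrix to a list of genes
#'
#' Matching is exact and case-sensitive; rows are returned in the requested
#' order. Used e.g. to restrict to a one-to-one ortholog list.
#'
#' @param expr Wide expression tibble (linear or log scale).
#' @param ids Character vector of unique gene ids.
#' @return The subset tibble, rows in the order of `ids`.
#' @export
subset_genes <- function(expr, ids) {
  if (anyDuplicated(ids) > 0) abort("requested gene ids must be unique")
  idx <- match(ids, expr$gene_id)
  if (anyNA(idx)) {
    miss <- ids[is.na(idx)]
    abort(paste0("gene id(s) not in matrix: ",
                 paste(head(miss, 10), collapse = ", ")))
  }
  out <- expr[idx, , drop = FALSE]
  attr(out, "pseudocount") <- attr(expr, "pseudocount")
  out
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path File with one gene id per line; blank lines ignored.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  ids <- readr::read_lines(path)
  ids[nzchar(ids)]
}

# genes x samples numeric matrix from a wide tibble
expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

values_to_expr <- function(m, gene_ids = rownames(m)) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}
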