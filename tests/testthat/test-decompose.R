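test_that("single-gene decomposition matches hand-worked and degenerate cases", {
  # 2x2 grid (organs x species): least-squares projection gives residuals of
  # +/-0.25 at all four cells
  d <- decompose_gene(matrix(c(1, 3, 2, 5), 2, 2))
  expect_equal(d$sst, 8.75)
  expect_equal(d$sso, 6.25)
  expect_equal(d$sss, 2.25)
  expect_equal(d$ssr, 0.25)
  expect_equal(c(d$p_o, d$p_s, d$p_r),
               c(0.714286, 0.257143, 0.028571), tolerance = 1e-6)
  # constant grid: zero total variation, proportions undefined
  z <- decompose_gene(matrix(5, 3, 4))
  expect_equal(z$sst, 0)
  expect_true(is.na(z$p_o))
  # row-constant grid (organ-only signal)
  r <- decompose_gene(matrix(rep(c(1, 2, 4), 5), 3, 5))
  expect_equal(r$p_o, 1)
  expect_equal(r$p_s, 0)
  expect_equal(r$p_r, 0)
  expect_error(decompose_gene(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("matrix-level decomposition agrees with the per-gene path and lm", {
  design <- make_design(organs = letters[1:4], species = LETTERS[1:5])
  sim <- single_class_sim("balanced", 40, design, seed = 21,
                          log_scale = TRUE)
  log_expr <- sim$expr
  all_d <- decompose_all(log_expr, design)
  y <- expr_values(log_expr)
  for (g in c(1, 17, 40)) {
    grid <- matrix(y[g, ], nrow = 4,
                   dimnames = list(attr(design, "organs"), NULL))
    # columns of y are species-major: reshape to organs x species
    grid <- matrix(y[g, ], nrow = 4)
    one <- decompose_gene(grid)
    expect_equal(all_d$sso[g], one$sso, tolerance = 1e-12)
    expect_equal(all_d$sss[g], one$sss, tolerance = 1e-12)
    expect_equal(all_d$ssr[g], one$ssr, tolerance = 1e-12)
  }
  # independent oracle: sequential sums of squares from lm/anova
  org <- factor(design$organ)
  spc <- factor(design$species)
  for (g in c(3, 25)) {
    a <- anova(stats::lm(y[g, ] ~ org + spc))
    expect_equal(all_d$sso[g], a["org", "Sum Sq"], tolerance = 1e-10)
    expect_equal(all_d$sss[g], a["spc", "Sum Sq"], tolerance = 1e-10)
    expect_equal(all_d$ssr[g], a["Residuals", "Sum Sq"], tolerance = 1e-10)
  }
})

test_that("dynamic range matches closed forms", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(0.99, 5, 0), s2 = c(99.99, 5, 0.99))
  dr <- dynamic_range(expr)
  expect_equal(dr$dynamic_range, c(2, 0, 2))
  expect_error(dynamic_range(expr[, 1]), "no sample")
})

test_that("classification applies thresholds inclusively and monotonically", {
  mk <- function(p_o, p_s, drv) {
    n <- length(p_o)
    decomp <- tibble::tibble(gene_id = sprintf("g%d", seq_len(n)),
                             sst = 1, sso = p_o, sss = p_s,
                             ssr = 1 - p_o - p_s,
                             p_o = p_o, p_s = p_s, p_r = 1 - p_o - p_s)
    dr <- tibble::tibble(gene_id = decomp$gene_id, dynamic_range = drv)
    classify_genes(decomp, dr)
  }
  got <- mk(p_o = c(0.6, 0.5, 0.2, 0.4, 0.9),
            p_s = c(0.2, 0.25, 0.6, 0.4, 0.02),
            drv = c(3, 3, 3, 3, 1))
  expect_equal(got$class, c("tvg", "tvg", "svg", "other_unconstrained",
                            "constrained"))
  # pre-intersection dominance mask ignores the dynamic range
  expect_true(got$dominant_organ[5])
  # zero-variance gene: dr is necessarily 0 -> constrained
  z <- mk(p_o = NA_real_, p_s = NA_real_, drv = 0)
  expect_equal(z$class, "constrained")
  # monotone in dr_min: raising it never un-constrains a gene
  loose <- mk(c(0.6, 0.9), c(0.2, 0.02), c(2.5, 2.1))
  strict <- classify_genes(
    dplyr::select(loose, "gene_id":"p_r"),
    tibble::tibble(gene_id = loose$gene_id,
                   dynamic_range = loose$dynamic_range),
    classification_thresholds(dr_min = 3))
  expect_true(all(strict$class[loose$class == "constrained"] ==
                    "constrained"))
  expect_true(all(strict$class %in% c("constrained", loose$class)))
})

test_that("cancelling a factor's variance zeroes its sum of squares", {
  design <- make_design()
  sim <- single_class_sim("balanced", 60, design, seed = 31,
                          log_scale = TRUE)
  no_org <- remove_factor_variance(sim$expr, design, "organ")
  d1 <- decompose_all(no_org, design)
  expect_lt(max(d1$sso), 1e-18)
  expect_true(all(d1$p_o[!is.na(d1$p_o)] < 1e-9))
  no_spc <- remove_factor_variance(sim$expr, design, "species")
  d2 <- decompose_all(no_spc, design)
  expect_lt(max(d2$sss), 1e-18)
  # species-dominated genes gain organ share when species variance is removed
  svg_sim <- single_class_sim("svg", 300, design, seed = 32,
                              log_scale = TRUE)
  before <- decompose_all(svg_sim$expr, design)
  after <- decompose_all(
    remove_factor_variance(svg_sim$expr, design, "species"), design)
  expect_gt(mean(after$p_o, na.rm = TRUE), mean(before$p_o, na.rm = TRUE))
  # gene constant within every organ maps to an all-zero row
  const <- tibble::tibble(gene_id = "g1")
  vals <- setNames(as.list(match(design$organ, attr(design, "organs"))),
                   design$sample_id)
  const <- dplyr::bind_cols(const, tibble::as_tibble(vals))
  zeroed <- remove_factor_variance(const, design, "organ")
  expect_true(all(expr_values(zeroed) == 0))
})

test_that("within-sample standardization gives exact zero mean, unit sd", {
  expr <- tibble::tibble(gene_id = c("a", "b", "c"),
                         s1 = c(1, 2, 3), s2 = c(5, 5, 6))
  std <- standardize_within_sample(expr)
  expect_equal(std$s1, c(-1, 0, 1))
  expect_equal(colMeans(expr_values(std)), c(s1 = 0, s2 = 0))
  expect_equal(apply(expr_values(std), 2, sd), c(s1 = 1, s2 = 1))
  expect_equal(expr_values(standardize_within_sample(std)),
               expr_values(std), tolerance = 1e-12)
  const <- dplyr::mutate(expr, s2 = 1)
  expect_error(standardize_within_sample(const), "constant sample")
})

test_that("pairwise decompositions cover all non-reference species", {
  design <- make_design()
  sim <- single_class_sim("balanced", 100, design,
                          tree = default_species_tree(), seed = 41,
                          log_scale = TRUE)
  pw <- pairwise_species_decomposition(sim$expr, design, "human")
  expect_setequal(unique(pw$species),
                  setdiff(attr(design, "species"), "human"))
  expect_equal(nrow(pw), 6 * 100)
  # conservation holds within every pair
  expect_lt(max(abs(pw$sst - (pw$sso + pw$sss + pw$ssr))), 1e-9)
  expect_error(pairwise_species_decomposition(sim$expr, design, "yeti"),
               "unknown reference")
  # organ exclusion drops that organ's samples
  pw2 <- pairwise_species_decomposition(sim$expr, design, "human",
                                        exclude_organs = "testis")
  expect_equal(nrow(pw2), 6 * 100)
})

test_that("duplicated species blocks yield zero species share", {
  design <- make_design(organs = c("brain", "liver", "heart"),
                        species = c("s1", "s2"))
  base <- withr::with_seed(7, matrix(rnorm(30), 10, 3))
  y <- cbind(base, base)  # s2 identical to s1
  colnames(y) <- design$sample_id
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%d", 1:10)),
                           tibble::as_tibble(y))
  pw <- pairwise_species_decomposition(expr, design, "s1")
  expect_lt(max(pw$p_s), 1e-12)
})
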