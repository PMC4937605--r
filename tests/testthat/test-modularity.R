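test_that("sample correlations hit exact collinearity cases", {
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- sample_correlations(expr)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  const <- dplyr::mutate(expr, b = 2)
  expect_error(sample_correlations(const), "constant sample")
})

test_that("network thresholding is strict and bookkeeping is consistent", {
  expr <- toy_expr(n_genes = 10)
  r <- sample_correlations(log_transform(expr))
  n <- ncol(r)
  empty <- build_network(r, 1)
  expect_equal(empty$m, 0)
  full <- build_network(r, min(r[upper.tri(r)]) - 0.01)
  expect_equal(full$m, n * (n - 1) / 2)
  expect_true(all(diag(full$adjacency) == 0))
  # strict: an edge exactly at the threshold is excluded under "gt"
  thr <- max(r[upper.tri(r)])
  expect_equal(build_network(r, thr)$m, 0)
  expect_gt(build_network(r, thr, rule = "ge")$m, 0)
  expect_equal(full$degrees, rowSums(full$adjacency))
})

test_that("modularity matches closed forms and term-by-term enumeration", {
  # single group: Q = 0
  g <- random_graph(8, 0.5, seed = 1)
  net <- structure(list(adjacency = g$A, nodes = as.character(1:8),
                        m = sum(g$A) / 2, degrees = rowSums(g$A),
                        threshold = NA), class = "sample_network")
  expect_equal(modularity_q(net, rep("x", 8)), 0, tolerance = 1e-14)
  # two disconnected single-edge components grouped by component: Q = 1/2
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- A2[3, 4] <- A2[4, 3] <- 1
  net2 <- structure(list(adjacency = A2, nodes = as.character(1:4),
                         m = 2, degrees = rowSums(A2), threshold = NA),
                    class = "sample_network")
  expect_equal(modularity_q(net2, c("a", "a", "b", "b")), 0.5)
  # c equal disconnected modules give 1 - 1/c: three triangles
  A3 <- matrix(0, 9, 9)
  for (b in 0:2) {
    idx <- 3 * b + 1:3
    A3[idx, idx] <- 1 - diag(3)
  }
  net3 <- structure(list(adjacency = A3, nodes = as.character(1:9),
                         m = 9, degrees = rowSums(A3), threshold = NA),
                    class = "sample_network")
  expect_equal(modularity_q(net3, rep(c("a", "b", "c"), each = 3)), 2 / 3)
  # path graph 1-2-3-4-5, groups {1,2,3} {4,5}: exhaustive enumeration
  A5 <- matrix(0, 5, 5)
  for (i in 1:4) A5[i, i + 1] <- A5[i + 1, i] <- 1
  net5 <- structure(list(adjacency = A5, nodes = as.character(1:5),
                         m = 4, degrees = rowSums(A5), threshold = NA),
                    class = "sample_network")
  grp <- c("a", "a", "a", "b", "b")
  expect_equal(modularity_q(net5, grp), modularity_bruteforce(A5, grp),
               tolerance = 1e-14)
  # no-edge network is undefined
  net0 <- structure(list(adjacency = matrix(0, 3, 3),
                         nodes = as.character(1:3), m = 0,
                         degrees = rep(0, 3), threshold = NA),
                    class = "sample_network")
  expect_error(modularity_q(net0, c("a", "b", "c")), "no edges")
})

test_that("modularity agrees with igraph and is label/order invariant", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    g <- random_graph(sample(5:12, 1), runif(1, 0.3, 0.8), seed = 100 + s)
    if (sum(g$A) == 0) next
    net <- structure(list(adjacency = g$A,
                          nodes = as.character(seq_len(nrow(g$A))),
                          m = sum(g$A) / 2, degrees = rowSums(g$A),
                          threshold = NA), class = "sample_network")
    q <- modularity_q(net, g$groups)
    ig <- igraph::graph_from_adjacency_matrix(g$A, mode = "undirected")
    expect_equal(q, igraph::modularity(ig, as.integer(factor(g$groups))),
                 tolerance = 1e-12)
    # relabeling groups leaves Q unchanged
    relab <- unname(setNames(sample(LETTERS[1:4]), letters[1:4])[g$groups])
    expect_equal(modularity_q(net, relab), q, tolerance = 1e-14)
    # permuting node order leaves Q unchanged
    p <- sample(nrow(g$A))
    netp <- structure(list(adjacency = g$A[p, p],
                           nodes = as.character(seq_along(p)),
                           m = net$m, degrees = rowSums(g$A)[p],
                           threshold = NA), class = "sample_network")
    expect_equal(modularity_q(netp, g$groups[p]), q, tolerance = 1e-14)
  }
})

test_that("modularity curve realizes requested edge counts and density", {
  design <- make_design()
  sim <- single_class_sim("tvg", 300, design, seed = 51)
  corr <- sample_correlations(log_transform(sim$expr))
  grid <- c(41, 120, 400, 861)
  curve <- modularity_curve(corr, design, grid)
  expect_equal(curve$edges, grid)
  expect_equal(curve$density, grid / choose(42, 2))
  # complete graph density is 1 and both groupings are computable
  expect_equal(curve$density[4], 1)
  expect_true(all(is.finite(curve$q_organ)))
  # flipping the diagonal convention changes Q but not the organ-vs-species
  # ordering on organ-dominated data
  net <- build_network(corr, curve$threshold[2])
  diag(net$adjacency) <- 1
  net$degrees <- rowSums(net$adjacency)
  net$m <- sum(net$adjacency) / 2
  organ <- setNames(design$organ, design$sample_id)
  species <- setNames(design$species, design$sample_id)
  q_alt <- c(modularity_q(net, organ), modularity_q(net, species))
  expect_false(isTRUE(all.equal(q_alt[1], curve$q_organ[2])))
  expect_gt(q_alt[1], q_alt[2])
  expect_gt(curve$q_organ[2], curve$q_species[2])
})
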