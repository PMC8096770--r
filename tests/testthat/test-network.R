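expr_fixture <- function(n_case = 60, n_ctrl = 40, seed = 5) {
  sim_expression(n_case = n_case, n_ctrl = n_ctrl, n_genes = 50,
                 n_blocks = 2, genes_per_block = 10, seed = seed)
}

test_that("z-transform centers and scales per gene, dropping constants", {
  x <- tibble::tibble(
    sample_id = c("a", "b", "c"), status = c(1L, 1L, 0L),
    g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(0, 1, 5)
  )
  z <- z_transform_genes(x)
  expect_false("g2" %in% names(z))  # constant gene dropped
  expect_equal(attr(z, "n_dropped"), 1L)
  # hand arithmetic for g1: mean 2, population sd sqrt(2/3)
  expect_equal(z$g1, (c(1, 2, 3) - 2) / sqrt(2 / 3), tolerance = 1e-12)
  for (g in c("g1", "g3")) {
    expect_equal(mean(z[[g]]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(z[[g]]^2)), 1, tolerance = 1e-12)
  }
})

test_that("feature selection finds a perfectly separating gene", {
  set.seed(1)
  n <- 200
  status <- rep(c(0L, 1L), each = n / 2)
  mat <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(NULL, paste0("g", 1:30)))
  mat[, "g1"] <- status * 4 + rnorm(n, sd = 0.1)  # near-perfect separator
  expr <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:n), status = status),
    tibble::as_tibble(mat)
  )
  hits <- vapply(1:5, function(s) {
    "g1" %in% select_discriminative_genes(expr, seed = s, num_trees = 200)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # no genes in, no genes out
  empty <- expr[, c("sample_id", "status")]
  expect_length(select_discriminative_genes(empty), 0)
})

test_that("case-only correlation graph keeps r >= 0.8 inclusively", {
  set.seed(2)
  n <- 100
  a <- rnorm(n)
  # construct b with exact correlation 0.8 to a
  resid <- rnorm(n)
  resid <- resid - a * sum(a * resid) / sum(a^2)
  b <- 0.8 * (a - mean(a)) / sd(a) +
    sqrt(1 - 0.64) * (resid - mean(resid)) / sd(resid)
  expr <- tibble::tibble(sample_id = paste0("s", 1:n),
                         status = 1L, ga = a, gb = b, gc = a)
  g <- case_correlation_graph(expr, r_min = 0.8)
  expect_true(igraph::are_adjacent(g, "ga", "gb"))   # exactly 0.8 kept
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("ga", "gc"))]
  expect_equal(w, 1)                                  # duplicated gene
  # independent noise genes make no 0.8 edges at n = 500
  set.seed(3)
  noise <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:500), status = 1L),
    tibble::as_tibble(matrix(rnorm(500 * 10), 500, 10,
                             dimnames = list(NULL, paste0("n", 1:10))))
  )
  expect_equal(igraph::ecount(case_correlation_graph(noise)), 0)
})

two_cliques <- function() {
  g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f)
  g
}

test_that("modularity matches hand values on canonical graphs", {
  g <- two_cliques()
  memb <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), igraph::V(g)$name)
  expect_equal(graph_modularity(g, memb), 0.5)
  expect_equal(graph_modularity(g, setNames(rep(1L, 6),
                                            igraph::V(g)$name)), 0)
  # complete graph, one community: Q = 0 for the trivial partition
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(graph_modularity(k5, setNames(rep(1L, 5), letters[1:5])), 0)
  expect_error(graph_modularity(g, memb[-1]), "cover")
})

test_that("modularity agrees with igraph's implementation on random graphs", {
  set.seed(4)
  for (i in 1:5) {
    g <- igraph::sample_gnp(12, 0.35)
    igraph::V(g)$name <- paste0("v", 1:12)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 1)
    memb <- sample(1:3, 12, replace = TRUE)
    names(memb) <- igraph::V(g)$name
    expect_equal(
      graph_modularity(g, memb),
      igraph::modularity(g, memb, weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("Louvain recovers canonical structures with matching Q", {
  g <- two_cliques()
  part <- detect_communities(g, seed = 1)
  expect_equal(length(attr(part, "sizes")), 2L)
  expect_equal(attr(part, "modularity"), 0.5)
  # the reported Q always equals an independent recomputation
  expect_equal(attr(part, "modularity"),
               graph_modularity(g, setNames(part$community, part$gene)),
               tolerance = 1e-12)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  p5 <- detect_communities(k5, seed = 1)
  expect_equal(length(attr(p5, "sizes")), 1L)
  expect_equal(attr(p5, "modularity"), 0)
  # isolated nodes become singleton communities
  gi <- igraph::make_graph(~ a - b) + igraph::vertices("z")
  pi <- detect_communities(gi, seed = 1)
  expect_equal(sort(pi$gene), c("a", "b", "z"))
  expect_equal(pi$community[pi$gene == "z"] %in% pi$community[pi$gene != "z"],
               FALSE)
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  # N = 20, K = 5, n = 4, k = 3 -> P = 155/4845
  expect_equal(pathpes:::hypergeom_tail(3, 4, 5, 20), 155 / 4845,
               tolerance = 1e-12)
  expect_equal(pathpes:::hypergeom_tail(0, 4, 5, 20), 1)
  # k = n = K is the minimal achievable p; verify against enumeration
  enum <- choose(15, 0) * choose(5, 5) / choose(20, 5)
  expect_equal(pathpes:::hypergeom_tail(5, 5, 5, 20), enum,
               tolerance = 1e-12)
  # monotone decreasing in k
  ps <- vapply(0:4, function(k) pathpes:::hypergeom_tail(k, 4, 5, 20),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("community enrichment finds the planted pathway per block", {
  expr <- expr_fixture(seed = 7)
  z <- z_transform_genes(expr)
  g <- case_correlation_graph(z)
  part <- detect_communities(g, seed = 1)
  truth <- attr(expr, "truth")
  block_sets <- pathpes:::new_geneset_collection(tibble::tibble(
    set_id = c("REACTOME_B1", "REACTOME_B2"), source = "REACTOME",
    n_genes = 10L,
    genes = list(truth$gene[which(truth$block == 1)],
                 truth$gene[which(truth$block == 2)])
  ))
  enr <- community_enrichment(part, block_sets)
  expect_true(all(enr$k <= pmin(enr$n, enr$K)))
  expect_equal(enr$p_bonferroni,
               pmin(1, enr$p_hyper * nrow(enr)))
  # each planted set's best hit is a genuine community with low p
  best <- enr[enr$k > 0, ]
  expect_true(all(best$p_hyper[best$k >= 8] < 1e-6))
  expect_error(community_enrichment(part, block_sets, universe = "zzz"),
               "universe")
})
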