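#' Z-transform an expression matrix gene-wise
#'
#' Centers every gene to mean zero and scales to standard deviation one
#' (population SD, i.e. divisor `n`). Genes with zero variance cannot be
#' scaled and are dropped; their count is recorded in the `n_dropped`
#' attribute.
#'
#' @param expr Tibble with `sample_id`, optionally `status`, and one numeric
#'   column per gene.
#' @return The transformed tibble (same shape minus dropped genes).
#' @export
z_transform_genes <- function(expr) {
  meta <- intersect(c("sample_id", "status"), names(expr))
  genes <- setdiff(names(expr), meta)
  if (nrow(expr) < 2) abort("need at least 2 samples to z-transform")
  mat <- as.matrix(expr[, genes, drop = FALSE])
  mu <- colMeans(mat)
  sdev <- sqrt(colMeans(sweep(mat, 2, mu)^2))  # divisor n
  keep <- sdev > 0
  mat <- sweep(sweep(mat[, keep, drop = FALSE], 2, mu[keep]), 2,
               sdev[keep], `/`)
  out <- dplyr::bind_cols(expr[, meta, drop = FALSE], as_tibble(mat))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Select genes that discriminate cases from controls
#'
#' Ranks genes by extremely-randomized-trees importance (ranger with the
#' `extratrees` split rule) for case/control classification and keeps those
#' whose impurity importance exceeds the mean importance. The selector is
#' deliberately simple and pluggable: pass any function of
#' `(expr_matrix, status)` returning per-gene importances via `importance_fun`.
#'
#' @param expr Expression tibble with `sample_id`, `status` and gene columns.
#' @param seed Integer seed for the tree ensemble.
#' @param num_trees Number of trees (default 500).
#' @param importance_fun Optional replacement importance function.
#' @return Character vector of selected genes; the full importance table is
#'   attached as attribute `importance`.
#' @export
select_discriminative_genes <- function(expr, seed = 1, num_trees = 500,
                                        importance_fun = NULL) {
  genes <- setdiff(names(expr), c("sample_id", "status"))
  if (length(genes) == 0L) return(character(0))
  if (length(unique(expr$status)) < 2) abort("both labels must be present")
  mat <- as.matrix(expr[, genes, drop = FALSE])
  imp <- if (is.null(importance_fun)) {
    fit <- ranger::ranger(
      x = mat, y = factor(expr$status),
      num.trees = num_trees, splitrule = "extratrees",
      importance = "impurity", seed = seed,
      num.threads = 1
    )
    fit$variable.importance
  } else {
    importance_fun(mat, expr$status)
  }
  keep <- names(imp)[imp > mean(imp)]
  structure(keep,
            importance = tibble(gene = names(imp),
                                importance = unname(imp)))
}

#' Case-only co-expression graph
#'
#' Computes all pairwise Pearson correlations among the provided genes using
#' case samples only and keeps an edge wherever `r >= r_min` (inclusive;
#' 0.8 by default, so retained edges are strongly positive). Edge weight is
#' the correlation. All genes stay as vertices, so uncorrelated genes become
#' isolated nodes.
#'
#' @param expr Expression tibble (`sample_id`, `status`, gene columns).
#' @param genes Genes to include (default: all gene columns).
#' @param r_min Inclusive correlation threshold.
#' @param cases_only Drop `status == 0` samples first (default TRUE).
#' @return An undirected weighted [igraph::graph] object.
#' @export
case_correlation_graph <- function(expr, genes = NULL, r_min = 0.8,
                                   cases_only = TRUE) {
  if (cases_only && "status" %in% names(expr)) {
    expr <- expr[expr$status == 1, , drop = FALSE]
  }
  if (nrow(expr) < 3) abort("need at least 3 case samples")
  genes <- genes %||% setdiff(names(expr), c("sample_id", "status"))
  mat <- as.matrix(expr[, genes, drop = FALSE])
  cm <- suppressWarnings(cor(mat))
  cm[!is.finite(cm)] <- 0
  adj <- ifelse(cm >= r_min, cm, 0)
  diag(adj) <- 0
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}

#' Louvain community detection
#'
#' Two-phase greedy modularity optimization on the (weighted) graph via
#' igraph's Louvain implementation; the node visit order is shuffled under
#' `seed` so runs are reproducible. Isolated nodes come back as singleton
#' communities. The reported modularity is recomputed independently with
#' [graph_modularity()].
#'
#' @param graph An igraph graph (weighted edges used when present).
#' @param seed Integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @param weighted Use edge weights (default TRUE); otherwise all edges
#'   count 1.
#' @return A `community_partition` tibble (`gene`, `community`) with
#'   attributes `modularity` and `sizes`; `tidy()`/`glance()` methods
#'   available.
#' @export
detect_communities <- function(graph, seed = 1, resolution = 1,
                               weighted = TRUE) {
  stopifnot(igraph::vcount(graph) > 0)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else {
    rep(1, igraph::ecount(graph))
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = if (length(w)) w else NULL,
                                resolution = resolution)
  membership <- igraph::membership(cl)
  out <- tibble(gene = names(membership),
                community = as.integer(membership))
  q <- graph_modularity(graph, setNames(out$community, out$gene),
                        weighted = weighted)
  structure(out,
            class = c("community_partition", class(tibble())),
            modularity = q,
            sizes = sort(table(out$community), decreasing = TRUE))
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c [ w_in(c) / (2W) - (w_tot(c) / (2W))^2 ]` where `w_in(c)` is
#' twice the within-community edge weight, `w_tot(c)` the total degree
#' weight of community `c`, and `W` the total edge weight.
#'
#' @param graph An igraph graph.
#' @param membership Named integer vector (names = vertex names) covering
#'   every vertex.
#' @param weighted Use edge weights when available.
#' @return Modularity `Q` in `[-1, 1]`.
#' @export
graph_modularity <- function(graph, membership, weighted = TRUE) {
  vn <- igraph::V(graph)$name
  if (!all(vn %in% names(membership))) {
    abort("partition must cover every graph node")
  }
  memb <- membership[vn]
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else {
    rep(1, nrow(el))
  }
  W <- sum(w)
  if (W == 0) return(0)
  same <- memb[el[, 1]] == memb[el[, 2]]
  # strength (weighted degree) per community
  strength <- tapply(c(w, w), c(memb[el[, 1]], memb[el[, 2]]), sum)
  q_in <- sum(w[same]) / W
  q_deg <- sum((strength / (2 * W))^2)
  unname(q_in - q_deg)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d genes in %d communities, Q = %.3f\n",
              nrow(x), length(attr(x, "sizes")), attr(x, "modularity")))
  NextMethod()
}

#' @export
tidy.community_partition <- function(x, ...) as_tibble(x)

#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_communities = length(attr(x, "sizes")),
         modularity = attr(x, "modularity"),
         largest_community = as.integer(attr(x, "sizes")[1]))
}

#' Hypergeometric pathway enrichment of communities
#'
#' For every (community, gene set) pair with nonzero overlap potential,
#' tests over-representation with the upper-tail hypergeometric
#' `P(X >= k)` given community size `n`, `K` annotated genes in the
#' universe of `N`, and Bonferroni-corrects over all tests performed
#' (communities x pathways).
#'
#' The universe defaults to the partitioned genes themselves (the genes
#' eligible to enter communities), which avoids selection-induced
#' inflation; pass a larger `universe` to override.
#'
#' @param partition A `community_partition`.
#' @param collection A `geneset_collection`.
#' @param universe Character vector of background genes (must contain every
#'   community gene).
#' @param min_community_size Skip smaller communities (default 3).
#' @return Tibble `community`, `set_id`, `k`, `n`, `K`, `N`, `p_hyper`,
#'   `p_bonferroni`, sorted by adjusted p.
#' @export
community_enrichment <- function(partition, collection,
                                 universe = partition$gene,
                                 min_community_size = 3) {
  if (!all(partition$gene %in% universe)) {
    abort("universe must contain every community gene")
  }
  N <- length(unique(universe))
  comms <- split(partition$gene, partition$community)
  comms <- comms[lengths(comms) >= min_community_size]
  sets <- purrr::map(collection$genes, ~ intersect(.x, universe))
  names(sets) <- collection$set_id
  rows <- purrr::imap(comms, function(members, cid) {
    n <- length(members)
    purrr::imap(sets, function(gs, sid) {
      K <- length(gs)
      k <- length(intersect(members, gs))
      tibble(community = as.integer(cid), set_id = sid,
             k = k, n = n, K = K, N = N,
             p_hyper = hypergeom_tail(k, n, K, N))
    }) %>% bind_rows()
  }) %>% bind_rows()
  n_tests <- nrow(rows)
  rows %>%
    mutate(p_bonferroni = pmin(1, .data$p_hyper * n_tests)) %>%
    arrange(.data$p_bonferroni, .data$p_hyper)
}

# Upper-tail hypergeometric P(X >= k) drawing n from N with K successes.
hypergeom_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
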