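make_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_gmt parses sets, collapses duplicates, infers sources", {
  path <- make_gmt(c(
    "REACTOME_ALPHA\tdesc\tSNCA\tLRRK2\tSNCA",
    "KEGG_LYSOSOME\tdesc\tGBA\tLAMP1",
    "MYSTERY_SET\tdesc\tPRKN"
  ))
  cc <- read_gmt(path)
  expect_s3_class(cc, "geneset_collection")
  expect_equal(nrow(cc), 3L)
  expect_equal(cc$genes[[1]], c("SNCA", "LRRK2"))  # duplicate collapsed
  expect_equal(cc$n_genes, c(2L, 2L, 1L))
  expect_equal(cc$source, c("REACTOME", "KEGG", "OTHER"))
  counts <- count_sets_by_source(cc)
  expect_equal(sum(counts$n_sets), nrow(cc))
})

test_that("read_gmt handles the empty file and flags malformed lines", {
  empty <- make_gmt(character(0))
  expect_equal(nrow(read_gmt(empty)), 0L)
  bad <- make_gmt(c("GOOD_SET\tdesc\tA", "ONLY_ONE_FIELD"))
  expect_error(read_gmt(bad), "line 2")
})

test_that("write_gmt / read_gmt round-trips, agreeing with fgsea's reader", {
  path <- make_gmt(c(
    "PID_FIRST\tdesc\tTP53\tEGFR\tMYC",
    "BIOCARTA_SECOND\tdesc\tAKT1"
  ))
  cc <- read_gmt(path)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cc, out)
  expect_equal(as.data.frame(read_gmt(out)), as.data.frame(cc))
  skip_if_not_installed("fgsea")
  oracle <- fgsea::gmtPathways(out)
  expect_equal(unname(oracle), cc$genes)
  expect_equal(names(oracle), cc$set_id)
})

variants_fx <- tibble::tibble(
  id = paste0("v", 1:6), chrom = c("chr1", "chr1", "chr1", "chr1",
                                   "chr2", "chr2"),
  pos = c(999, 1000, 1999, 2000, 1500, 5000),
  a1 = "A", a2 = "G", maf = 0.2
)
genes_fx <- tibble::tibble(
  symbol = c("GA", "GB", "GC"),
  chrom = c("chr1", "chr1", "chr2"),
  start = c(1000, 1500, 1000), end = c(2000, 2500, 2000)
)

test_that("variant-to-gene mapping uses half-open intervals and dedups", {
  hit <- map_variants_to_gene_set(variants_fx, genes_fx, "GA")
  expect_equal(hit$variant_ids, c("v2", "v3"))  # 1000 in, 2000 out
  expect_equal(hit$n_skipped_genes, 0L)
  # overlapping member genes count a shared variant once
  both <- map_variants_to_gene_set(variants_fx, genes_fx, c("GA", "GB"))
  expect_equal(sort(both$variant_ids), c("v2", "v3", "v4"))
  # unannotated genes are skipped and tallied
  none <- map_variants_to_gene_set(variants_fx, genes_fx,
                                   c("NOPE1", "NOPE2"))
  expect_equal(none$variant_ids, character(0))
  expect_equal(none$n_skipped_genes, 2L)
})

test_that("variant mapping is order-independent", {
  cc <- pathpes:::new_geneset_collection(tibble::tibble(
    set_id = c("S1", "S2"), source = "OTHER", n_genes = c(2L, 1L),
    genes = list(c("GA", "GB"), "GC")
  ))
  m1 <- map_variants_to_sets(variants_fx, genes_fx, cc)
  shuffled <- variants_fx[sample(nrow(variants_fx)), ]
  m2 <- map_variants_to_sets(shuffled, genes_fx, cc)
  expect_equal(lapply(m1, sort), lapply(m2, sort))
})

test_that("exclude_loci removes a 1 Mb window per chromosome, idempotently", {
  v <- tibble::tibble(
    id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr1"),
    pos = c(10.9e6, 11.1e6, 10e6), a1 = "A", a2 = "G", maf = 0.3
  )
  hits <- tibble::tibble(chrom = "chr1", pos = 10e6)
  kept <- exclude_loci(v, hits)
  expect_equal(kept$id, "b")  # 0.9 Mb excluded, 1.1 Mb retained
  # other chromosome never touched
  hits2 <- tibble::tibble(chrom = "chr2", pos = 10e6)
  expect_equal(exclude_loci(v, hits2)$id, v$id)
  # idempotence
  expect_equal(exclude_loci(kept, hits), kept)
})

test_that("exclude_loci never removes variants beyond the window", {
  set.seed(42)
  v <- tibble::tibble(
    id = paste0("r", 1:300),
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    pos = sample.int(5e7, 300), a1 = "A", a2 = "G", maf = 0.1
  )
  hits <- tibble::tibble(chrom = c("chr1", "chr2"),
                         pos = c(2.2e7, 3.7e7))
  kept <- exclude_loci(v, hits, window_bp = 1e6)
  removed <- dplyr::anti_join(v, kept, by = "id")
  near <- function(row) any(row$chrom == hits$chrom &
                              abs(row$pos - hits$pos) <= 1e6)
  expect_true(all(vapply(seq_len(nrow(removed)),
                         function(i) near(removed[i, ]), logical(1))))
  expect_false(any(vapply(seq_len(nrow(kept)),
                          function(i) near(kept[i, ]), logical(1))))
})

test_that("pleiotropy ranking counts memberships with lexicographic ties", {
  sets <- c(list(c("A", paste0("g", 1:19))),
            replicate(4, "A", simplify = FALSE),
            lapply(20:99, function(i) paste0("g", i)))
  cc <- pathpes:::new_geneset_collection(tibble::tibble(
    set_id = paste0("S", seq_along(sets)), source = "OTHER",
    n_genes = lengths(sets), genes = sets
  ))
  top <- rank_pleiotropic_genes(cc, top_fraction = 0.01)
  expect_equal(top$gene, "A")  # 100 genes, top 1% = 1 gene, A in 5 sets
  expect_equal(top$n_sets, 5L)
  all_of_them <- rank_pleiotropic_genes(cc, top_fraction = 1)
  expect_equal(nrow(all_of_them), 100L)
  # ties broken lexicographically at the cut
  cc2 <- pathpes:::new_geneset_collection(tibble::tibble(
    set_id = "S1", source = "OTHER", n_genes = 3L,
    genes = list(c("zeta", "beta", "alpha"))
  ))
  expect_equal(rank_pleiotropic_genes(cc2, 0.3)$gene, "alpha")
})

test_that("gene annotation invariants are enforced", {
  expect_error(pathpes:::validate_gene_table(
    tibble::tibble(symbol = "G", chrom = "chr1", start = 10, end = 10)),
    "start < end")
  expect_error(pathpes:::validate_gene_table(
    tibble::tibble(symbol = c("G", "G"), chrom = "chr1",
                   start = c(1, 5), end = c(4, 9))),
    "duplicated")
})
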