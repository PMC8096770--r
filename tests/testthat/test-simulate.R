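test_that("genotypes honor HWE, LD blocks, bounds and determinism", {
  layout <- sim_variant_layout(n_blocks = 2, block_size = 4,
                               block_r = 0, maf_range = c(0.5, 0.5),
                               seed = 1)
  panel <- sim_genotypes(layout, 10000, seed = 2)
  # HWE at MAF 0.5: genotype frequencies 0.25/0.5/0.25 within 3 SDs
  tab <- table(factor(panel$dosage[, 1], levels = 0:2)) / 10000
  sds <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) < 3 * sds))
  # r = 0 blocks: inter-variant r2 at the 1/n scale
  r2 <- cor(panel$dosage[, 1], panel$dosage[, 2])^2
  expect_lt(r2, 25 / 10000)
  # determinism and dosage bounds
  panel2 <- sim_genotypes(layout, 10000, seed = 2)
  expect_identical(panel$dosage, panel2$dosage)
  expect_true(all(panel$dosage %in% 0:2))
  # correlated blocks really are correlated
  lay_r <- sim_variant_layout(n_blocks = 1, block_size = 2, block_r = 0.8,
                              maf_range = c(0.3, 0.3), seed = 3)
  pr <- sim_genotypes(lay_r, 4000, seed = 4)
  expect_gt(cor(pr$dosage[, 1], pr$dosage[, 2]), 0.4)
})

test_that("liability-threshold phenotypes hit the target prevalence", {
  layout <- sim_variant_layout(n_blocks = 5, block_size = 2, seed = 5)
  panel <- sim_genotypes(layout, 5000, seed = 6)
  # zero effects: case fraction ~ K within 3 binomial SDs
  ph <- sim_case_control(panel, K = 0.2, seed = 7)
  expect_lt(abs(mean(ph$status) - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  ph5 <- sim_case_control(panel, K = 0.5, seed = 8)
  expect_lt(abs(mean(ph5$status) - 0.5), 3 * sqrt(0.25 / 5000))
  # covariates present and finite
  expect_true(all(c("age", "sex", "PC1", "PC5") %in% names(ph)))
  expect_true(all(is.finite(ph$age)))
  # planted effects separate cases from controls (AUC > 0.5)
  eff <- setNames(rep(0.5, 4), layout$variants$id[1:4])
  ph_eff <- sim_case_control(panel, eff, K = 0.2, h2 = 0.5, seed = 9)
  g <- as.numeric(panel$dosage[, names(eff)] %*% eff)
  auc <- mean(outer(g[ph_eff$status == 1], g[ph_eff$status == 0], `>`) +
                0.5 * outer(g[ph_eff$status == 1],
                            g[ph_eff$status == 0], `==`))
  expect_gt(auc, 0.6)
})

test_that("summary statistics are calibrated and track the panel", {
  layout <- sim_variant_layout(n_blocks = 40, block_size = 2,
                               block_r = 0, seed = 10)
  panel <- sim_genotypes(layout, 3000, seed = 11)
  ph <- sim_case_control(panel, K = 0.3, n_pcs = 0, seed = 12)
  ss <- sim_summary_stats(panel, ph)
  # frequency equals the panel allele frequency exactly
  expect_equal(ss$freq, unname(colMeans(panel$dosage[, ss$id]) / 2))
  # null p-values uniform
  expect_gt(ks.test(ss$p, "punif")$p.value, 0.01)
  # planted causal variant gains |z| with sample size
  eff <- setNames(0.4, layout$variants$id[1])
  z_at <- function(n, seed) {
    p <- sim_genotypes(layout, n, seed = seed)
    phe <- sim_case_control(p, eff, K = 0.3, h2 = 0.3, n_pcs = 0,
                            seed = seed + 1L)
    s <- sim_summary_stats(p, phe)
    abs(s$beta[s$id == names(eff)] / s$se[s$id == names(eff)])
  }
  expect_gt(z_at(4000, 20), z_at(500, 22))
})

test_that("expression blocks correlate among cases only", {
  expr <- sim_expression(n_case = 500, n_ctrl = 200, n_genes = 40,
                         n_blocks = 2, genes_per_block = 10,
                         block_r = 0.9, seed = 13)
  truth <- attr(expr, "truth")
  expect_equal(nrow(truth), 40L)
  b1 <- truth$gene[which(truth$block == 1)]
  cases <- expr[expr$status == 1, ]
  ctrls <- expr[expr$status == 0, ]
  cm <- cor(as.matrix(cases[, b1]))
  within_r <- mean(cm[upper.tri(cm)])
  expect_lt(abs(within_r - 0.9), 0.05)
  # between-block correlation near zero; controls unstructured
  b2 <- truth$gene[which(truth$block == 2)]
  between <- cor(as.matrix(cases[, b1]), as.matrix(cases[, b2]))
  expect_lt(abs(mean(between)), 0.05)
  cmc <- cor(as.matrix(ctrls[, b1]))
  expect_lt(abs(mean(cmc[upper.tri(cmc)])), 0.1)
})

test_that("specificity rows sum to 1 with the planted coupling only", {
  genes <- sprintf("g%04d", 1:2000)
  sp <- sim_specificity(genes, c("planted", paste0("ct", 1:11)),
                        planted = "planted", seed = 14)
  expect_equal(rowSums(sp$specificity[, -1]), rep(1, 2000))
  planted_cor <- cor(sp$specificity$planted, sp$effect_sd,
                     method = "spearman")
  expect_gt(planted_cor, 0.9)
  null_cors <- vapply(paste0("ct", 1:11), function(ct) {
    cor(sp$specificity[[ct]], sp$effect_sd, method = "spearman")
  }, numeric(1))
  expect_lt(max(abs(null_cors)), 0.2)
})

test_that("eQTL scenarios produce the intended summary structure", {
  q <- sim_eqtl(n_genes = 5, scenario = "null", n_cis = 20, seed = 15)
  expect_equal(length(q$ld_list), 5L)
  expect_equal(nrow(q$eqtl), 100L)
  for (m in q$ld_list) {
    expect_equal(unname(diag(m)), rep(1, 20))
    expect_equal(m, t(m))
  }
  # null scenario: GWAS p uniform over genes x snps
  expect_gt(ks.test(q$gwas$p, "punif")$p.value, 0.001)
  # mediation: top-SNP ratio recovers b_xy per gene
  qm <- sim_eqtl(n_genes = 40, scenario = "mediation", b_xy = 0.2,
                 seed = 16)
  scan <- smr_scan(qm$eqtl, qm$gwas, qm$ld_list)
  expect_lt(abs(median(scan$b_smr) - 0.2), 0.02)
})

test_that("generated tables round-trip through the package readers", {
  st <- sim_pes_study(n_ref = 300, n_train = 200, n_test = 100,
                      n_blocks = 6, n_sets = 2, seed = 17)
  ss_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(st$sumstats, ss_path, progress = FALSE)
  expect_equal(as.data.frame(read_summary_stats(ss_path)),
               as.data.frame(st$sumstats))
  v_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(st$layout$variants, v_path, progress = FALSE)
  expect_equal(as.data.frame(read_variant_table(v_path)),
               as.data.frame(st$layout$variants))
  bed_path <- withr::local_tempfile(fileext = ".bed")
  readr::write_tsv(st$layout$genes[, c("chrom", "start", "end", "symbol")],
                   bed_path, col_names = FALSE, progress = FALSE)
  bed <- read_gene_bed(bed_path)
  expect_equal(as.data.frame(bed),
               as.data.frame(st$layout$genes[, c("symbol", "chrom",
                                                 "start", "end")]))
})
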