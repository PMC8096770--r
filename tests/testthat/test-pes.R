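# Small deterministic panel used across the polygenic-score tests.
tiny_panel <- function() {
  dosage <- matrix(
    c(2, 1, 0, 1,
      1, 0, 2, 2,
      0, 2, 1, 0),
    nrow = 4, ncol = 3,
    dimnames = list(paste0("s", 1:4), paste0("v", 1:3))
  )
  variants <- tibble::tibble(
    id = paste0("v", 1:3), chrom = "chr1",
    pos = c(100e3, 200e3, 600e3), a1 = "A", a2 = "G", maf = 0.3
  )
  genotype_panel(dosage, variants)
}

test_that("summary-stat filter applies inclusive p and exclusive MAF bounds", {
  ss <- tibble::tibble(
    id = paste0("v", 1:10),
    p = c(0.05, 0.051, rep(c(0.01, 0.2), 4)),
    freq = c(0.3, 0.3, 0.01, 0.01, 0.95, 0.05, 0.5, 0.005, 0.2, 0.2)
  )
  kept <- filter_summary_stats(ss)
  # p passes for v1 (0.05 inclusive), v3, v5, v7, v9; the MAF rule then
  # drops v3 (maf = 0.01, strict >) and keeps v1, v5 (maf 0.05), v7, v9
  expect_equal(kept$id, c("v1", "v5", "v7", "v9"))
})

test_that("greedy LD clumping follows the p-ordered index rule", {
  # three SNPs: best at 100 kb, correlated one at 200 kb (within window),
  # independent one at 600 kb (outside window anyway)
  set.seed(7)
  n <- 400
  x1 <- rbinom(n, 2, 0.3)
  x2 <- ifelse(runif(n) < 0.75, x1, rbinom(n, 2, 0.3))  # r2 ~ 0.5
  x3 <- rbinom(n, 2, 0.3)
  dosage <- cbind(v1 = x1, v2 = x2, v3 = x3)
  rownames(dosage) <- paste0("s", 1:n)
  panel <- genotype_panel(dosage, tiny_panel()$variants)
  expect_gt(cor(x1, x2)^2, 0.1)
  cand <- tibble::tibble(id = c("v1", "v2", "v3"),
                         p = c(1e-8, 1e-4, 1e-3))
  expect_equal(ld_clump(cand, panel), c("v1", "v3"))
  # a single candidate survives trivially
  expect_equal(ld_clump(cand[1, ], panel), "v1")
  # all pairwise r2 below threshold: everything kept
  cand2 <- tibble::tibble(id = c("v1", "v3"), p = c(1e-3, 1e-8))
  expect_setequal(ld_clump(cand2, panel), c("v1", "v3"))
  # unknown id is a named error
  expect_error(ld_clump(tibble::tibble(id = "nope", p = 0.1), panel),
               "nope")
})

test_that("polygenic scores are the per-SNP-averaged weighted allele dose", {
  panel <- tiny_panel()
  w <- tibble::tibble(id = c("v1", "v2", "v3"), effect_allele = "A",
                      beta = c(0.1, -0.2, 0))
  sc <- compute_pes(panel, w, c("v1", "v2"))
  # sample s1: (0.1*2 - 0.2*1)/2 = 0
  expect_equal(sc$score[1], 0)
  # single SNP, dosage 2, beta 0.3
  w2 <- tibble::tibble(id = "v1", effect_allele = "A", beta = 0.3)
  expect_equal(compute_pes(panel, w2, "v1")$score[1], 0.6)
  # all-zero betas give all-zero scores
  w0 <- tibble::tibble(id = c("v1", "v2"), effect_allele = "A", beta = 0)
  expect_equal(compute_pes(panel, w0, c("v1", "v2"))$score, rep(0, 4))
  # raw-sum normalization is the documented alternative
  expect_equal(compute_pes(panel, w, c("v1", "v2"),
                           normalize = "sum")$score[1], 0)
  expect_equal(compute_pes(panel, w2, "v1", normalize = "sum")$score,
               compute_pes(panel, w2, "v1")$score)
})

test_that("scores are invariant to panel allele coding and to ordering", {
  panel <- tiny_panel()
  w <- tibble::tibble(id = c("v1", "v2"), effect_allele = "A",
                      beta = c(0.4, -0.7))
  base <- compute_pes(panel, w, c("v1", "v2"))
  # flip which allele the panel counts for v2
  d2 <- panel$dosage
  d2[, "v2"] <- 2 - d2[, "v2"]
  v2 <- panel$variants
  v2[v2$id == "v2", c("a1", "a2")] <- list("G", "A")
  flipped <- genotype_panel(d2, v2)
  expect_equal(compute_pes(flipped, w, c("v1", "v2"))$score, base$score)
  # permuting samples and variants permutes but never changes scores
  perm <- c(3, 1, 4, 2)
  pp <- genotype_panel(panel$dosage[perm, c("v2", "v1", "v3")],
                       panel$variants)
  sc_p <- compute_pes(pp, w, c("v1", "v2"))
  expect_equal(sc_p$score[match(base$sample_id, sc_p$sample_id)],
               base$score)
})

test_that("missing dosages drop out of both sums; all-missing is flagged", {
  panel <- tiny_panel()
  d <- panel$dosage
  d[1, "v2"] <- NA
  d[2, ] <- NA
  p2 <- genotype_panel(d, panel$variants)
  w <- tibble::tibble(id = c("v1", "v2"), effect_allele = "A",
                      beta = c(0.1, -0.2))
  sc <- compute_pes(p2, w, c("v1", "v2"))
  expect_equal(sc$score[1], 0.1 * 2 / 1)   # only v1 observed
  expect_true(is.na(sc$score[2]))
  expect_equal(attr(sc, "dropped"), "s2")
})

test_that("logistic association matches an independent ML optimizer", {
  set.seed(11)
  n <- 40
  ph <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    status = rep(c(0L, 1L), each = n / 2),
    age = rnorm(n, 60, 8)
  )
  score <- rnorm(n) + 0.8 * ph$status
  fit <- fit_pes_association(ph, score, covariates = "age")
  # independent oracle: direct likelihood maximization over all coefs
  X <- cbind(1, ph$age, as.numeric(scale(score)))
  nll <- function(b) {
    eta <- X %*% b
    -sum(ph$status * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    mu <- plogis(X %*% b)
    -as.numeric(crossprod(X, ph$status - mu))
  }
  opt <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
  expect_equal(fit$beta, opt$par[3], tolerance = 1e-6)
  expect_equal(fit$loglik_full, -opt$value, tolerance = 1e-8)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$beta)
  expect_equal(glance(fit)$nobs, n)
})

test_that("null scores give near-zero effect and R2; L0 = L1 gives R2 = 0", {
  set.seed(21)
  n <- 600
  ph <- tibble::tibble(sample_id = paste0("s", 1:n),
                       status = rbinom(n, 1, 0.4))
  fit <- fit_pes_association(ph, rnorm(n), covariates = character(0))
  expect_lt(abs(fit$beta), 0.2)
  expect_lt(fit$r2_nagelkerke, 0.01)
  expect_equal(pathpes:::nagelkerke_r2(-100, -100, 200), 0)
  expect_error(fit_pes_association(ph, rep(1, n),
                                   covariates = character(0)),
               "zero variance")
})

test_that("liability conversion matches the closed form and is monotone", {
  expect_equal(liability_r2(0, 0.01, 0.4), 0)
  # K = P = 0.5: theta = 0, C = 0.25 / dnorm(0)^2
  C <- 0.25 / dnorm(0)^2
  for (r2 in c(0.05, 0.2, 0.6)) {
    expect_equal(liability_r2(r2, 0.5, 0.5), C * r2, tolerance = 1e-12)
  }
  grid <- seq(0, 1, by = 0.01)
  vals <- liability_r2(grid, K = 0.005, P = 0.4)
  expect_true(all(diff(vals) > 0))
  expect_error(liability_r2(0.1, 0, 0.5), "strictly within")
  expect_error(liability_r2(0.1, 0.5, 1), "strictly within")
})

test_that("permutation p-values respect the add-one formula and the seed", {
  set.seed(31)
  n <- 200
  ph <- tibble::tibble(sample_id = paste0("s", 1:n),
                       status = rep(c(0L, 1L), each = n / 2))
  strong <- rnorm(n, mean = 3 * ph$status)  # observed z beats every perm
  res <- permutation_pvalue(ph, strong, covariates = character(0),
                            n_perm = 99, seed = 5)
  expect_equal(res$p_empirical, 1 / 100)
  res2 <- permutation_pvalue(ph, strong, covariates = character(0),
                             n_perm = 99, seed = 5)
  expect_identical(res, res2)  # deterministic given seed
  null <- permutation_pvalue(ph, rnorm(n), covariates = character(0),
                             n_perm = 49, seed = 9)
  expect_gte(null$p_empirical, 1 / 50)
  expect_lte(null$p_empirical, 1)
})

test_that("pathway scan reports rows per phase and zero-variant sets", {
  st <- sim_pes_study(n_ref = 400, n_train = 400, n_test = 200,
                      n_blocks = 12, n_sets = 4, h2 = 0.5, seed = 2)
  # a set mapped to no variants stays in the scan and the denominator
  vm <- st$variant_map
  vm[[st$collection$set_id[2]]] <- character(0)
  sc <- scan_pathway_pes(st$collection, vm, st$sumstats,
                         st$train_panel, st$train_pheno,
                         st$test_panel, st$test_pheno,
                         prevalence = 0.2, n_perm = 30, seed = 1)
  thr <- attr(sc, "thresholds")
  expect_equal(thr$scan, 0.05 / 4)
  tr <- sc[sc$phase == "training", ]
  expect_equal(nrow(tr), 4L)
  empty_row <- tr[tr$set_id == st$collection$set_id[2], ]
  expect_equal(empty_row$n_snp, 0L)
  expect_true(is.na(empty_row$p_empirical))
  expect_true(all(tr$p_empirical >= 1 / 31, na.rm = TRUE))
  expect_equal(scan_thresholds(sc)$n_tests[1], 4)
})

test_that("training and testing cohorts must be disjoint", {
  st <- sim_pes_study(n_ref = 200, n_train = 200, n_test = 100,
                      n_blocks = 6, n_sets = 2, seed = 3)
  expect_error(
    scan_pathway_pes(st$collection, st$variant_map, st$sumstats,
                     st$train_panel, st$train_pheno,
                     st$train_panel, st$train_pheno),
    "disjoint")
})
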