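# Synthetic-data generators.  These define the study conditions under which
# the pipeline is exercised: LD-blocked genotypes in Hardy-Weinberg
# equilibrium via a Gaussian threshold copula, liability-threshold
# case/control status with risk concentrated in designated gene sets,
# blocked case-only correlation structure in expression, Dirichlet cell-type
# specificity with a planted specificity-effect coupling, and eQTL/GWAS
# summary statistics drawn from their exact asymptotic distribution under
# mediation, linkage or null scenarios.  Every generator is a pure function
# of its arguments and seed.

with_seed <- function(seed, code) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(code)
}

#' Variant layout: LD blocks, positions, allele frequencies
#'
#' Fixes the genetic map shared by all simulated cohorts: variants are
#' organized in LD blocks (compound-symmetric latent correlation `block_r`
#' within a block, independence between blocks), placed 10 kb apart within a
#' block with 2 Mb between blocks, 10 blocks per chromosome, and each block
#' is spanned by one gene.
#'
#' @param n_blocks Number of LD blocks (= genes).
#' @param block_size Variants per block.
#' @param block_r Within-block latent correlation.
#' @param maf_range MAF drawn uniformly from this range.
#' @param seed Integer seed.
#' @return List with `variants` (id, chrom, pos, a1, a2, maf, block),
#'   `genes` (symbol, chrom, start, end — BED convention), `block_r`.
#' @export
sim_variant_layout <- function(n_blocks = 100, block_size = 5,
                               block_r = 0.5, maf_range = c(0.05, 0.5),
                               seed = 1) {
  with_seed(seed, {
    blocks_per_chrom <- 10
    block <- rep(seq_len(n_blocks), each = block_size)
    within <- rep(seq_len(block_size), times = n_blocks)
    chrom <- paste0("chr", (block - 1) %/% blocks_per_chrom + 1)
    block_on_chrom <- (block - 1) %% blocks_per_chrom
    pos <- 1e6 + block_on_chrom * 2e6 + (within - 1) * 1e4
    maf <- runif(n_blocks * block_size, maf_range[1], maf_range[2])
    variants <- tibble(
      id = sprintf("rs%d_%d", block, within),
      chrom = chrom, pos = pos,
      a1 = "A", a2 = "G", maf = maf, block = block
    )
    genes <- variants %>%
      group_by(.data$block) %>%
      summarise(chrom = dplyr::first(.data$chrom),
                start = min(.data$pos) - 1,
                end = max(.data$pos) + 1, .groups = "drop") %>%
      mutate(symbol = sprintf("GENE%03d", .data$block)) %>%
      select("symbol", "chrom", "start", "end", "block")
    list(variants = variants, genes = genes, block_r = block_r)
  })
}

#' Simulate an LD-blocked genotype cohort in HWE
#'
#' Per block, two independent latent multivariate-normal haplotype draws with
#' compound-symmetric correlation are thresholded at each variant's MAF and
#' summed, yielding additive dosages in Hardy-Weinberg equilibrium with the
#' configured LD. Deterministic per seed.
#'
#' @param layout A [sim_variant_layout()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param prefix Sample-id prefix.
#' @return A [genotype_panel()].
#' @export
sim_genotypes <- function(layout, n, seed = 1, prefix = "S") {
  with_seed(seed, {
    v <- layout$variants
    r <- layout$block_r
    dosage <- matrix(0L, nrow = n, ncol = nrow(v),
                     dimnames = list(sprintf("%s%05d", prefix, seq_len(n)),
                                     v$id))
    for (b in unique(v$block)) {
      idx <- which(v$block == b)
      m <- length(idx)
      thr <- qnorm(v$maf[idx])
      hap <- matrix(0L, n, m)
      for (h in 1:2) {
        # compound-symmetric latent: sqrt(r) shared + sqrt(1-r) own
        shared <- rnorm(n)
        z <- sqrt(r) * shared +
          sqrt(1 - r) * matrix(rnorm(n * m), n, m)
        hap <- hap + (sweep(z, 2, thr, `<`)) * 1L
      }
      dosage[, idx] <- hap
    }
    genotype_panel(dosage, v)
  })
}

#' Liability-threshold case/control phenotypes
#'
#' Liability = standardized genetic score (weighted by `effects`) scaled to
#' heritability `h2`, plus independent normal noise; a sample is a case when
#' its liability exceeds `qnorm(1 - K)`. Attaches age (onset for cases,
#' examination for controls), sex, and the leading principal components of
#' the dosage matrix as covariates.
#'
#' @param panel A [genotype_panel()].
#' @param effects Named numeric vector of per-variant liability effects
#'   (names = variant ids); empty/zero for the global null.
#' @param K Population prevalence on the liability scale (default 0.2, the
#'   test-scale default so case counts stay usable at moderate n; the
#'   epidemiological 0.005 is exercised in the liability-conversion
#'   formula itself).
#' @param h2 Liability-scale heritability captured by `effects`.
#' @param n_pcs Number of genotype principal components attached.
#' @param seed Integer seed.
#' @return Phenotype tibble: `sample_id`, `status`, `age`, `sex`,
#'   `PC1..PCk`.
#' @export
sim_case_control <- function(panel, effects = numeric(0), K = 0.2,
                             h2 = 0.3, n_pcs = 5, seed = 1) {
  stopifnot(K > 0, K < 1)
  with_seed(seed, {
    n <- nrow(panel$dosage)
    g <- rep(0, n)
    if (length(effects) > 0 && any(effects != 0)) {
      ids <- intersect(names(effects), colnames(panel$dosage))
      if (length(ids) == 0L) abort("effects must be keyed to panel variants")
      g <- as.numeric(panel$dosage[, ids, drop = FALSE] %*% effects[ids])
    }
    liability <- if (sd(g) > 0) {
      sqrt(h2) * as.numeric(scale(g)) + rnorm(n, 0, sqrt(1 - h2))
    } else {
      rnorm(n)
    }
    status <- as.integer(liability > qnorm(1 - K))
    sex <- rbinom(n, 1, 0.5)
    age <- ifelse(status == 1, rnorm(n, 62, 9), rnorm(n, 66, 10))
    base <- tibble(sample_id = rownames(panel$dosage), status = status,
                   age = age, sex = sex)
    if (n_pcs == 0) return(base)
    poly <- apply(panel$dosage, 2, sd) > 0
    pcs <- prcomp(scale(panel$dosage[, poly, drop = FALSE]),
                  center = FALSE,
                  scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    dplyr::bind_cols(base, as_tibble(pcs))
  })
}

#' Per-variant GWAS summary statistics from a cohort
#'
#' Single-SNP binary-outcome association for every variant via the logistic
#' score test (the statistic large-cohort GWAS engines use), with the
#' one-step Newton effect estimate as beta (log odds per counted allele):
#' `U_j = g_j' (y - ybar)`, `V_j = ybar (1 - ybar) ||g_j - gbar_j||^2`,
#' `z = U/sqrt(V)`, `beta = U/V`, `se = 1/sqrt(V)`. Effect-allele frequency
#' equals the panel allele frequency exactly. Monomorphic variants are
#' dropped. Fully vectorized, so reference cohorts of tens of thousands of
#' samples are cheap.
#'
#' @param panel A [genotype_panel()].
#' @param phenotype Matching phenotype tibble.
#' @return Summary-statistics tibble `id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `freq`.
#' @export
sim_summary_stats <- function(panel, phenotype) {
  y <- phenotype$status[match(rownames(panel$dosage),
                              phenotype$sample_id)]
  freq <- colMeans(panel$dosage) / 2
  keep <- freq > 0 & freq < 1
  G <- panel$dosage[, keep, drop = FALSE]
  ybar <- mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  U <- as.numeric(crossprod(Gc, y - ybar))
  V <- ybar * (1 - ybar) * colSums(Gc^2)
  z <- U / sqrt(V)
  v <- panel$variants[keep, , drop = FALSE]
  tibble(
    id = colnames(G),
    effect_allele = v$a1, other_allele = v$a2,
    beta = U / V, se = 1 / sqrt(V),
    p = 2 * pnorm(abs(z), lower.tail = FALSE),
    freq = unname(freq[keep])
  )
}

#' Assign genes to gene sets
#'
#' Partitions the layout's genes round-robin into `n_sets` disjoint sets;
#' set ids carry a REACTOME-style prefix so source inference has something
#' to chew on.
#'
#' @param layout A [sim_variant_layout()].
#' @param n_sets Number of sets.
#' @return A `geneset_collection`.
#' @export
sim_gene_sets <- function(layout, n_sets = 50) {
  genes <- layout$genes$symbol
  idx <- rep(seq_len(n_sets), length.out = length(genes))
  sets <- split(genes, idx)
  new_geneset_collection(tibble(
    set_id = sprintf("REACTOME_SYNTH_SET_%03d", seq_len(n_sets)),
    source = "REACTOME",
    n_genes = lengths(sets),
    genes = unname(sets)
  ))
}

#' Complete synthetic polygenic-score study
#'
#' Generates everything a two-phase pathway scan needs: a shared variant
#' layout, three independent cohorts (reference for weights, training,
#' testing), liability-threshold phenotypes with risk concentrated in one
#' designated causal gene set (or none, under the global null), reference
#' summary statistics, the gene-set collection and the variant map.
#'
#' @param n_ref,n_train,n_test Cohort sizes.
#' @param n_blocks,block_size,block_r,maf_range Layout parameters.
#' @param n_sets Number of gene sets.
#' @param causal_set Index of the planted causal set, or `NA` for the global
#'   null.
#' @param h2 Liability heritability concentrated in the causal set.
#' @param K Prevalence.
#' @param n_pcs Principal components attached to phenotypes.
#' @param seed Master seed (cohort seeds derived from it).
#' @return List: `layout`, `collection`, `variant_map`, `sumstats`,
#'   `train_panel`, `train_pheno`, `test_panel`, `test_pheno`,
#'   `causal_set_id`, `effects`.
#' @export
sim_pes_study <- function(n_ref = 2000, n_train = 2000, n_test = 1000,
                          n_blocks = 100, block_size = 5, block_r = 0.5,
                          maf_range = c(0.05, 0.5), n_sets = 50,
                          causal_set = 1, h2 = 0.3, K = 0.2, n_pcs = 5,
                          seed = 1) {
  layout <- sim_variant_layout(n_blocks, block_size, block_r, maf_range,
                               seed = seed)
  collection <- sim_gene_sets(layout, n_sets)
  variant_map <- map_variants_to_sets(layout$variants, layout$genes,
                                      collection)
  effects <- numeric(0)
  causal_set_id <- NA_character_
  if (!is.na(causal_set)) {
    causal_set_id <- collection$set_id[causal_set]
    causal_ids <- variant_map[[causal_set_id]]
    effects <- with_seed(seed + 7L,
                         setNames(rnorm(length(causal_ids)), causal_ids))
  }
  ref_panel <- sim_genotypes(layout, n_ref, seed = seed + 1L, prefix = "R")
  ref_pheno <- sim_case_control(ref_panel, effects, K = K, h2 = h2,
                                n_pcs = 0, seed = seed + 2L)
  train_panel <- sim_genotypes(layout, n_train, seed = seed + 3L,
                               prefix = "T")
  train_pheno <- sim_case_control(train_panel, effects, K = K, h2 = h2,
                                  n_pcs = n_pcs, seed = seed + 4L)
  test_panel <- sim_genotypes(layout, n_test, seed = seed + 5L,
                              prefix = "V")
  test_pheno <- sim_case_control(test_panel, effects, K = K, h2 = h2,
                                 n_pcs = n_pcs, seed = seed + 6L)
  list(layout = layout, collection = collection, variant_map = variant_map,
       sumstats = sim_summary_stats(ref_panel, ref_pheno),
       train_panel = train_panel, train_pheno = train_pheno,
       test_panel = test_panel, test_pheno = test_pheno,
       causal_set_id = causal_set_id, effects = effects)
}

#' Synthetic rare-variant burden study
#'
#' Independent rare variants (binomial dosages at low MAF), genes holding
#' several variants each, gene sets over those genes, and a
#' liability-threshold phenotype with positive effects planted on one set's
#' rare alleles. Functional categories (`missense`, `lof`, `cadd_gt12`) are
#' assigned at random, with deliberate overlap (a variant may carry two
#' labels). MAC/MAF are computed in the combined case + control panel.
#'
#' @param n Samples.
#' @param n_genes Genes.
#' @param variants_per_gene Rare variants per gene.
#' @param n_sets Gene sets (disjoint, round-robin).
#' @param causal_set Planted set index or `NA` for null.
#' @param effect Liability effect per planted rare allele.
#' @param maf_range Rare MAF range.
#' @param K Prevalence.
#' @param seed Integer seed.
#' @return List: `collection`, `rare_variants` (long format), `panel`,
#'   `phenotype`, `causal_set_id`.
#' @export
sim_burden_study <- function(n = 1000, n_genes = 40, variants_per_gene = 8,
                             n_sets = 10, causal_set = 1, effect = 0.8,
                             maf_range = c(0.002, 0.02), K = 0.2,
                             seed = 1) {
  with_seed(seed, {
    m <- n_genes * variants_per_gene
    maf <- runif(m, maf_range[1], maf_range[2])
    dosage <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
                     dimnames = list(sprintf("B%05d", seq_len(n)),
                                     sprintf("rv%04d", seq_len(m))))
    gene <- rep(sprintf("RGENE%03d", seq_len(n_genes)),
                each = variants_per_gene)
    variants <- tibble(
      id = colnames(dosage), chrom = "chr1",
      pos = seq_len(m) * 1000, a1 = "A", a2 = "G",
      maf = pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
    )
    panel <- genotype_panel(dosage, variants)
    # long-format annotation with overlapping categories
    primary <- sample(c("missense", "lof"), m, replace = TRUE,
                      prob = c(0.7, 0.3))
    ann <- tibble(id = variants$id, chrom = variants$chrom,
                  pos = variants$pos, gene = gene, category = primary)
    cadd <- sample(m, round(m * 0.3))
    ann <- bind_rows(ann, mutate(ann[cadd, ], category = "cadd_gt12"))
    ann$mac <- as.integer(pmin(colSums(dosage),
                               2 * n - colSums(dosage)))[match(ann$id, variants$id)]
    ann$maf <- variants$maf[match(ann$id, variants$id)]
    sets <- split(unique(gene), rep(seq_len(n_sets),
                                    length.out = n_genes))
    collection <- new_geneset_collection(tibble(
      set_id = sprintf("KEGG_SYNTH_BURDEN_%02d", seq_len(n_sets)),
      source = "KEGG", n_genes = lengths(sets), genes = unname(sets)
    ))
    causal_set_id <- NA_character_
    effects <- numeric(0)
    if (!is.na(causal_set)) {
      causal_set_id <- collection$set_id[causal_set]
      causal_ids <- ann$id[ann$gene %in% collection$genes[[causal_set]]]
      effects <- setNames(rep(effect, length(unique(causal_ids))),
                          unique(causal_ids))
    }
    phenotype <- sim_case_control(panel, effects, K = K, h2 = 0.25,
                                  n_pcs = 3, seed = seed + 1L)
    list(collection = collection, rare_variants = ann, panel = panel,
         phenotype = phenotype, causal_set_id = causal_set_id)
  })
}

#' Synthetic case/control expression matrix with planted communities
#'
#' Case samples draw blocked multivariate-normal expression (within-block
#' correlation `block_r`, independence between blocks); controls draw
#' independent noise, so correlation structure exists only among cases.
#' Block genes additionally get a case-control mean shift `delta` so they
#' are discoverable by case/control feature selection. The gene-to-block
#' ground truth is attached.
#'
#' @param n_case,n_ctrl Sample counts.
#' @param n_genes Total genes.
#' @param n_blocks Planted co-expression blocks.
#' @param genes_per_block Genes per block (remaining genes are unstructured
#'   noise).
#' @param block_r Within-block correlation among cases.
#' @param delta Case mean shift of block genes.
#' @param seed Integer seed.
#' @return Expression tibble (`sample_id`, `status`, gene columns) with
#'   attribute `truth` (tibble gene, block; block `NA` = noise gene).
#' @export
sim_expression <- function(n_case = 120, n_ctrl = 80, n_genes = 120,
                           n_blocks = 4, genes_per_block = 15,
                           block_r = 0.9, delta = 1, seed = 1) {
  with_seed(seed, {
    structured <- n_blocks * genes_per_block
    stopifnot(structured <= n_genes)
    gene_names <- sprintf("EG%04d", seq_len(n_genes))
    block_of <- c(rep(seq_len(n_blocks), each = genes_per_block),
                  rep(NA_integer_, n_genes - structured))
    make_block <- function(ns, m) {
      shared <- rnorm(ns)
      sqrt(block_r) * shared + sqrt(1 - block_r) * matrix(rnorm(ns * m), ns, m)
    }
    case_mat <- matrix(rnorm(n_case * n_genes), n_case, n_genes)
    for (b in seq_len(n_blocks)) {
      cols <- which(block_of == b)
      case_mat[, cols] <- make_block(n_case, length(cols)) + delta
    }
    ctrl_mat <- matrix(rnorm(n_ctrl * n_genes), n_ctrl, n_genes)
    mat <- rbind(case_mat, ctrl_mat)
    colnames(mat) <- gene_names
    out <- dplyr::bind_cols(
      tibble(sample_id = sprintf("E%05d", seq_len(n_case + n_ctrl)),
             status = rep(c(1L, 0L), c(n_case, n_ctrl))),
      as_tibble(mat)
    )
    attr(out, "truth") <- tibble(gene = gene_names, block = block_of)
    out
  })
}

#' Synthetic cell-type specificity with a planted effect coupling
#'
#' Per-gene Dirichlet rows over cell types; for the planted cell type,
#' per-gene variant effect standard deviations scale linearly with that
#' column's specificity (`effect_sd = base_sd * specificity`), while other
#' cell types are uncoupled from effects.
#'
#' @param genes Character vector of gene symbols.
#' @param cell_types Character vector of cell-type names.
#' @param planted The coupled cell type (must be in `cell_types`).
#' @param concentration Dirichlet concentration (smaller = spikier rows).
#' @param base_sd Effect-SD scale for the planted coupling.
#' @param baseline Polygenic baseline added to the coupling
#'   (`effect_sd = base_sd * (baseline + specificity)`), so every gene
#'   carries some effect and the specificity gradient rides on top of it.
#' @param seed Integer seed.
#' @return List: `specificity` tibble (`gene` + cell-type columns) and
#'   `effect_sd` (named per-gene SDs).
#' @export
sim_specificity <- function(genes, cell_types, planted = cell_types[1],
                            concentration = 0.5, base_sd = 1,
                            baseline = 0, seed = 1) {
  stopifnot(planted %in% cell_types)
  with_seed(seed, {
    k <- length(cell_types)
    g <- matrix(rgamma(length(genes) * k, shape = concentration), ncol = k)
    s <- g / rowSums(g)
    colnames(s) <- cell_types
    spec <- dplyr::bind_cols(tibble(gene = genes), as_tibble(s))
    list(specificity = spec,
         effect_sd = setNames(base_sd * (baseline + s[, planted]), genes))
  })
}

#' Complete synthetic cell-type specificity study
#'
#' Couples [sim_specificity()] to the genotype/phenotype generators: per-gene
#' variant effects are drawn with standard deviation proportional to the
#' planted cell type's specificity, so polygenic R2 should rise across that
#' cell type's specificity deciles (and only that one). Generates reference,
#' training and testing cohorts plus reference summary statistics.
#'
#' @param n_ref,n_train,n_test Cohort sizes.
#' @param n_blocks,block_size,block_r Layout parameters (one gene per
#'   block).
#' @param cell_types Cell-type names; the first is the planted one.
#' @param h2 Liability heritability of the coupled effects.
#' @param K Prevalence.
#' @param n_pcs Principal components attached.
#' @param concentration Dirichlet concentration of the specificity rows
#'   (larger = smoother rows, hence a smoother R2 gradient over deciles).
#' @param seed Master seed.
#' @return List: `layout`, `specificity`, `planted`, `sumstats`,
#'   `train_panel`, `train_pheno`, `test_panel`, `test_pheno`, `effects`.
#' @export
sim_celltype_study <- function(n_ref = 20000, n_train = 3000,
                               n_test = 2500,
                               n_blocks = 400, block_size = 4,
                               block_r = 0.5,
                               cell_types = c("planted_type",
                                              paste0("other_",
                                                     letters[1:11])),
                               h2 = 0.9, K = 0.2, n_pcs = 5,
                               concentration = 3, seed = 1) {
  layout <- sim_variant_layout(n_blocks, block_size, block_r, seed = seed)
  sp <- sim_specificity(layout$genes$symbol, cell_types,
                        planted = cell_types[1],
                        concentration = concentration, baseline = 0.15,
                        seed = seed + 10L)
  effects <- with_seed(seed + 11L, {
    sd_per_variant <- sp$effect_sd[
      layout$genes$symbol[match(layout$variants$block,
                                layout$genes$block)]]
    setNames(rnorm(nrow(layout$variants), 0, sd_per_variant),
             layout$variants$id)
  })
  ref_panel <- sim_genotypes(layout, n_ref, seed = seed + 1L, prefix = "R")
  ref_pheno <- sim_case_control(ref_panel, effects, K = K, h2 = h2,
                                n_pcs = 0, seed = seed + 2L)
  train_panel <- sim_genotypes(layout, n_train, seed = seed + 3L,
                               prefix = "T")
  train_pheno <- sim_case_control(train_panel, effects, K = K, h2 = h2,
                                  n_pcs = n_pcs, seed = seed + 4L)
  test_panel <- sim_genotypes(layout, n_test, seed = seed + 5L,
                              prefix = "V")
  test_pheno <- sim_case_control(test_panel, effects, K = K, h2 = h2,
                                 n_pcs = n_pcs, seed = seed + 6L)
  list(layout = layout, specificity = sp$specificity,
       planted = cell_types[1],
       sumstats = sim_summary_stats(ref_panel, ref_pheno),
       train_panel = train_panel, train_pheno = train_pheno,
       test_panel = test_panel, test_pheno = test_pheno,
       effects = effects)
}

#' Synthetic eQTL + GWAS summary statistics for SMR/HEIDI
#'
#' Per gene, a cis region of `n_cis` SNPs with AR(1) LD (`r_ij =
#' ld_decay^|i-j|`). Estimated effects are drawn from their exact asymptotic
#' distribution: marginal true effects follow from the causal configuration
#' through the LD matrix, and estimation noise is multivariate normal with
#' covariance `se^2 * R` within each study (eQTL and GWAS samples
#' independent). Scenarios: `mediation` (one shared causal variant drives
#' expression, which drives the trait with effect `b_xy`), `linkage` (two
#' LD-linked variants drive expression and trait separately) and `null`
#' (no trait effect). The trait side is a liability-scale quantitative
#' trait so the planted `b_xy` is recovered without logistic attenuation.
#'
#' @param n_genes Genes to simulate.
#' @param scenario `"mediation"`, `"linkage"` or `"null"`.
#' @param n_cis Cis SNPs per gene.
#' @param b_xy Causal expression-on-trait effect (mediation).
#' @param b_eqtl Causal variant's effect on expression (SD units).
#' @param n_eqtl,n_gwas Effective sample sizes setting the SEs.
#' @param ld_decay AR(1) LD parameter.
#' @param seed Integer seed.
#' @return List: `eqtl` tibble (`gene`, `snp`, `b_eqtl`, `se_eqtl`,
#'   `p_eqtl`, `tissue`), `gwas` summary-statistics tibble, `ld_list`
#'   (per-gene LD matrices), `scenario`.
#' @export
sim_eqtl <- function(n_genes = 50, scenario = c("mediation", "linkage",
                                                "null"),
                     n_cis = 30, b_xy = 0.2, b_eqtl = 0.4,
                     n_eqtl = 5000, n_gwas = 20000, ld_decay = 0.85,
                     seed = 1) {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    R <- ld_decay^abs(outer(seq_len(n_cis), seq_len(n_cis), `-`))
    Rch <- chol(R)
    se_e <- 1 / sqrt(n_eqtl)
    se_g <- 1 / sqrt(n_gwas)
    eqtl_rows <- vector("list", n_genes)
    gwas_rows <- vector("list", n_genes)
    ld_list <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gene <- sprintf("QGENE%03d", g)
      snps <- sprintf("%s_snp%02d", gene, seq_len(n_cis))
      dimnames(R) <- list(snps, snps)
      causal <- sample(5:(n_cis - 5), 1)
      true_e <- R[, causal] * b_eqtl
      true_g <- switch(
        scenario,
        mediation = b_xy * true_e,
        linkage = {
          causal2 <- causal + sample(c(-2, 2), 1)  # r ~ ld_decay^2
          R[, causal2] * (b_xy * b_eqtl)  # same marginal scale, other site
        },
        null = rep(0, n_cis)
      )
      b_e_hat <- true_e + as.numeric(t(Rch) %*% rnorm(n_cis)) * se_e
      b_g_hat <- true_g + as.numeric(t(Rch) %*% rnorm(n_cis)) * se_g
      eqtl_rows[[g]] <- tibble(
        gene = gene, snp = snps, b_eqtl = b_e_hat, se_eqtl = se_e,
        p_eqtl = 2 * pnorm(abs(b_e_hat / se_e), lower.tail = FALSE),
        tissue = "synthetic"
      )
      gwas_rows[[g]] <- tibble(
        id = snps, effect_allele = "A", other_allele = "G",
        beta = b_g_hat, se = se_g,
        p = 2 * pnorm(abs(b_g_hat / se_g), lower.tail = FALSE),
        freq = 0.3
      )
      ld_list[[g]] <- R
      names(ld_list)[g] <- gene
    }
    list(eqtl = bind_rows(eqtl_rows), gwas = bind_rows(gwas_rows),
         ld_list = ld_list, scenario = scenario)
  })
}
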