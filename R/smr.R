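#' Summary-data-based Mendelian randomization test
#'
#' Tests whether a variant's disease effect is mediated by expression using
#' the top cis-eQTL as the instrument: the effect of expression on disease is
#' `b_smr = b_gwas / b_eqtl` (change in log odds per SD of expression), with
#' `T_SMR = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)` referred to a 1-df
#' chi-square and `se_smr = |b_smr| / sqrt(T_SMR)`.
#'
#' Vectorized over genes.
#'
#' @param b_gwas,se_gwas GWAS effect and standard error of the instrument.
#' @param b_eqtl,se_eqtl eQTL effect and standard error of the instrument.
#' @return Tibble `b_smr`, `se_smr`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  stopifnot(all(se_gwas > 0), all(se_eqtl > 0))
  z_gwas <- b_gwas / se_gwas
  z_eqtl <- b_eqtl / se_eqtl
  if (any(z_eqtl == 0)) abort("z_eqtl must be nonzero (no valid instrument)")
  t_smr <- (z_gwas^2 * z_eqtl^2) / (z_gwas^2 + z_eqtl^2)
  b_smr <- b_gwas / b_eqtl
  tibble(
    b_smr = b_smr,
    se_smr = ifelse(t_smr > 0, abs(b_smr) / sqrt(t_smr), NA_real_),
    t_smr = t_smr,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE)
  )
}

#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Distinguishes a single shared causal variant (mediation/pleiotropy at one
#' site) from linkage of distinct causal variants. For every eligible cis
#' SNP `i`, `b_xy(i) = b_gwas(i) / b_eqtl(i)` is compared with the top SNP's
#' estimate; the differences `d_i` have a covariance determined by the LD
#' correlations and both studies' standard errors (delta method), and the
#' statistic `sum z_d(i)^2` is referred to its weighted chi-square null
#' distribution via [quadform_pvalue()]. Small p (below 0.01 by convention)
#' marks heterogeneity, i.e. a gene failing HEIDI.
#'
#' Eligible SNPs are cis records with LD `r^2` to the top SNP inside
#' `r2_window` (defaults 0.05-0.9, excluding near-duplicates of the top SNP
#' and near-independent SNPs); at most `max_snps` are used, keeping the
#' strongest eQTLs. Fewer than 3 eligible SNPs makes the test not
#' assessable (`NA` with a flag).
#'
#' @param top One-row tibble/list with the instrument's `b_gwas`, `se_gwas`,
#'   `b_eqtl`, `se_eqtl` and `snp`.
#' @param cis Tibble of cis SNPs (`snp`, `b_gwas`, `se_gwas`, `b_eqtl`,
#'   `se_eqtl`), excluding or including the top SNP (it is removed).
#' @param ld Signed LD correlation matrix with dimnames covering `snp`s and
#'   the top SNP.
#' @param r2_window Inclusive-exclusive eligibility window on `r^2` with the
#'   top SNP.
#' @param max_snps Cap on SNPs used (strongest `|z_eqtl|` kept).
#' @return List `p_heidi`, `n_snps`, `assessable`.
#' @export
heidi_test <- function(top, cis, ld, r2_window = c(0.05, 0.9),
                       max_snps = 20) {
  cis <- cis[cis$snp != top$snp, , drop = FALSE]
  r_top <- ld[cis$snp, top$snp]
  r2 <- r_top^2
  elig <- r2 > r2_window[1] & r2 < r2_window[2]
  cis <- cis[elig, , drop = FALSE]
  if (nrow(cis) > max_snps) {
    z_e <- abs(cis$b_eqtl / cis$se_eqtl)
    cis <- cis[order(-z_e)[seq_len(max_snps)], , drop = FALSE]
  }
  if (nrow(cis) < 3) {
    return(list(p_heidi = NA_real_, n_snps = nrow(cis), assessable = FALSE))
  }
  snps <- c(top$snp, cis$snp)
  R <- ld[snps, snps]
  b_g <- c(top$b_gwas, cis$b_gwas)
  se_g <- c(top$se_gwas, cis$se_gwas)
  b_e <- c(top$b_eqtl, cis$b_eqtl)
  se_e <- c(top$se_eqtl, cis$se_eqtl)
  bxy <- b_g / b_e
  # delta-method covariance of the b_xy estimates (GWAS and eQTL samples
  # independent; within-study estimates correlated through LD)
  cov_xy <- (R * outer(se_g, se_g) + outer(bxy, bxy) * R * outer(se_e, se_e)) /
    outer(b_e, b_e)
  k <- length(snps)
  d <- bxy[-1] - bxy[1]
  V <- cov_xy[-1, -1, drop = FALSE] -
    matrix(cov_xy[-1, 1], k - 1, k - 1) -
    t(matrix(cov_xy[-1, 1], k - 1, k - 1)) +
    cov_xy[1, 1]
  V <- (V + t(V)) / 2
  sdv <- sqrt(diag(V))
  z_d <- d / sdv
  stat <- sum(z_d^2)
  corr <- V / outer(sdv, sdv)
  lambda <- tryCatch(
    clean_lambda(eigen((corr + t(corr)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values),
    error = function(e) NULL
  )
  if (is.null(lambda)) {
    # singular covariance: match first two moments to a scaled chi-square
    p <- pchisq(stat / 1, df = k - 1, lower.tail = FALSE)
    return(list(p_heidi = p, n_snps = k - 1, assessable = TRUE,
                flagged = TRUE))
  }
  list(p_heidi = as.numeric(quadform_pvalue(stat, lambda)),
       n_snps = k - 1, assessable = TRUE, flagged = FALSE)
}

#' SMR + HEIDI scan over genes
#'
#' Runs [smr_test()] per gene using its top cis-eQTL (smallest eQTL p) as
#' instrument and [heidi_test()] on the remaining cis SNPs. The pass flag
#' combines Bonferroni significance within the tested gene group
#' (`p_smr < alpha / n_genes`) with surviving HEIDI
#' (`p_heidi >= heidi_alpha`, not-assessable treated as surviving, as the
#' filter can only be applied where it is defined).
#'
#' @param eqtl Tibble of cis-eQTL records: `gene`, `snp`, `b_eqtl`,
#'   `se_eqtl`, `p_eqtl`, optional `tissue`.
#' @param gwas Summary statistics tibble keyed by `id` with `beta`, `se`.
#' @param ld_list Named list (by gene) of signed LD matrices for that gene's
#'   cis SNPs.
#' @param alpha Family-wise level for the per-group Bonferroni (default
#'   0.05).
#' @param heidi_alpha HEIDI rejection level (default 0.01).
#' @param r2_window,max_snps Passed to [heidi_test()].
#' @return An `smr_scan` tibble: `gene`, `top_snp`, `b_smr`, `se_smr`,
#'   `p_smr`, `p_heidi`, `n_heidi_snps`, `pass`, `tissue`.
#' @export
smr_scan <- function(eqtl, gwas, ld_list, alpha = 0.05, heidi_alpha = 0.01,
                     r2_window = c(0.05, 0.9), max_snps = 20) {
  genes <- unique(eqtl$gene)
  n_genes <- length(genes)
  rows <- purrr::map(genes, function(g) {
    rec <- eqtl[eqtl$gene == g, , drop = FALSE]
    rec <- rec[rec$snp %in% gwas$id, , drop = FALSE]
    if (nrow(rec) == 0L) return(NULL)
    gw <- gwas[match(rec$snp, gwas$id), , drop = FALSE]
    rec$b_gwas <- gw$beta
    rec$se_gwas <- gw$se
    top_i <- which.min(rec$p_eqtl)
    top <- rec[top_i, , drop = FALSE]
    sm <- smr_test(top$b_gwas, top$se_gwas, top$b_eqtl, top$se_eqtl)
    hd <- if (g %in% names(ld_list)) {
      heidi_test(top, rec, ld_list[[g]], r2_window, max_snps)
    } else {
      list(p_heidi = NA_real_, n_snps = 0L, assessable = FALSE)
    }
    tibble(gene = g, top_snp = top$snp,
           b_smr = sm$b_smr, se_smr = sm$se_smr, p_smr = sm$p_smr,
           p_heidi = hd$p_heidi, n_heidi_snps = hd$n_snps,
           tissue = if ("tissue" %in% names(top)) top$tissue else NA_character_)
  })
  out <- bind_rows(rows)
  out$pass <- out$p_smr < alpha / n_genes &
    (is.na(out$p_heidi) | out$p_heidi >= heidi_alpha)
  structure(out,
            class = c("smr_scan", class(tibble())),
            thresholds = list(alpha = alpha, n_genes = n_genes,
                              smr = alpha / n_genes,
                              heidi = heidi_alpha))
}

#' Chi-square enrichment of significant QTL genes in a gene set
#'
#' One-degree-of-freedom goodness-of-fit comparison of the observed number
#' of SMR-significant genes in a set against the expectation under the
#' background rate. The upper-tail chi-square p is reported for an excess
#' (`observed >= expected`); deficits are reported on the other side
#' (`p >= 0.5`), since only over-representation is of interest.
#'
#' @param n_tested Genes tested in the set (>= 1).
#' @param n_significant Genes passing SMR + HEIDI in the set.
#' @param background_rate Genome-wide proportion of significant genes, in
#'   (0, 1).
#' @return Tibble `n_tested`, `n_significant`, `expected`, `chi2`, `p`.
#' @export
set_enrichment_chisq <- function(n_tested, n_significant, background_rate) {
  if (background_rate <= 0 || background_rate >= 1) {
    abort("background_rate must lie in (0, 1)")
  }
  stopifnot(n_tested >= 1, n_significant <= n_tested)
  expected <- background_rate * n_tested
  exp_neg <- n_tested - expected
  chi2 <- (n_significant - expected)^2 / expected +
    ((n_tested - n_significant) - exp_neg)^2 / exp_neg
  tail_p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- if (n_significant >= expected) tail_p else 1 - tail_p / 2
  tibble(n_tested = n_tested, n_significant = n_significant,
         expected = expected, chi2 = chi2, p = p)
}

#' Intersect SMR-prioritized genes with network communities
#'
#' Set-exact overlap of genes passing SMR + HEIDI with the genes assigned to
#' expression communities — the cross-omic prioritization step.
#'
#' @param smr An `smr_scan` result.
#' @param partition A `community_partition`.
#' @return Tibble of passing genes found in communities, with their
#'   community id.
#' @export
smr_community_overlap <- function(smr, partition) {
  passing <- smr$gene[!is.na(smr$pass) & smr$pass]
  partition %>%
    as_tibble() %>%
    filter(.data$gene %in% passing) %>%
    arrange(.data$community, .data$gene)
}
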