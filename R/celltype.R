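#' Cell-type expression specificity
#'
#' Converts mean expression per (gene, cell type) into specificity scores:
#' `s_gc = e_gc / sum_c' e_gc'`, the proportion of a gene's total expression
#' found in one cell type. Each row sums to one; genes with zero total
#' expression are dropped (count recorded in attribute `n_dropped`).
#'
#' @param mean_expr Tibble with `gene` and one nonnegative numeric column per
#'   cell type.
#' @return Tibble of the same shape with specificity values.
#' @export
compute_specificity <- function(mean_expr) {
  cts <- setdiff(names(mean_expr), "gene")
  mat <- as.matrix(mean_expr[, cts, drop = FALSE])
  if (any(mat < 0)) abort("expression values must be nonnegative")
  tot <- rowSums(mat)
  keep <- tot > 0
  out <- dplyr::bind_cols(
    mean_expr[keep, "gene", drop = FALSE],
    as_tibble(sweep(mat[keep, , drop = FALSE], 1, tot[keep], `/`))
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Assign genes to specificity deciles for one cell type
#'
#' Ranks genes by ascending specificity and cuts them into `n_bins`
#' equal-count bins (decile 1 = least specific, 10 = most specific). Tied
#' values share the bin of their mean rank. Genes with zero specificity in
#' the cell type are excluded before binning.
#'
#' @param specificity Specificity tibble from [compute_specificity()].
#' @param cell_type Name of the cell-type column to bin on.
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @return Tibble `gene`, `specificity`, `decile`.
#' @export
assign_specificity_deciles <- function(specificity, cell_type, n_bins = 10) {
  s <- specificity[[cell_type]]
  keep <- s > 0
  s <- s[keep]
  genes <- specificity$gene[keep]
  if (length(s) < n_bins) {
    abort(sprintf("need at least %d genes with nonzero specificity", n_bins))
  }
  if (length(unique(s)) == 1L) {
    abort("degenerate specificity: all values identical, cannot form deciles")
  }
  r <- rank(s, ties.method = "average")
  decile <- pmin(pmax(ceiling(r / length(s) * n_bins), 1L), n_bins)
  tibble(gene = genes, specificity = s, decile = as.integer(decile))
}

#' Per-decile polygenic R2 for one cell type
#'
#' For each specificity decile, maps reference-filtered variants into that
#' decile's gene bodies and runs the polygenic-score stack (clump, score,
#' logistic fit, liability conversion) on the given cohort. Deciles with no
#' usable variants are recorded as `(r2 = 0, n_snp = 0)` and flagged.
#'
#' @param assignment Decile assignment from [assign_specificity_deciles()].
#' @param genes Gene annotation tibble (`symbol`, `chrom`, `start`, `end`).
#' @param sumstats Reference summary statistics.
#' @param panel Cohort [genotype_panel()].
#' @param phenotype Cohort phenotype tibble.
#' @param prevalence Population prevalence for the liability conversion.
#' @param n_pcs,p_max,maf_min,r2_max,window_bp As in [scan_pathway_pes()].
#' @return Tibble `decile`, `r2_liability`, `n_snp`, `flagged`.
#' @export
decile_prs_r2 <- function(assignment, genes, sumstats, panel, phenotype,
                          prevalence = 0.005, n_pcs = 20,
                          p_max = 0.05, maf_min = 0.01,
                          r2_max = 0.1, window_bp = 250000) {
  sumstats_f <- filter_summary_stats(sumstats, p_max, maf_min)
  covs <- default_covariates(phenotype, n_pcs)
  deciles <- sort(unique(assignment$decile))
  purrr::map(deciles, function(d) {
    dg <- assignment$gene[assignment$decile == d]
    mapped <- map_variants_to_gene_set(panel$variants, genes, dg)
    cand <- sumstats_f[sumstats_f$id %in% mapped$variant_ids, , drop = FALSE]
    if (nrow(cand) == 0L) {
      return(tibble(decile = d, r2_liability = 0, n_snp = 0L,
                    flagged = TRUE))
    }
    res <- tryCatch({
      idx <- ld_clump(cand, panel, r2_max = r2_max, window_bp = window_bp)
      sc <- compute_pes(panel, sumstats_f, idx)
      fit <- fit_pes_association(phenotype, sc, covs)
      P <- mean(phenotype$status)
      tibble(decile = d,
             r2_liability = liability_r2(min(fit$r2_nagelkerke, 1),
                                         prevalence, P),
             n_snp = length(idx), flagged = FALSE)
    }, error = function(e) {
      tibble(decile = d, r2_liability = 0, n_snp = 0L, flagged = TRUE)
    })
    res
  }) %>% bind_rows()
}

#' Trend of polygenic R2 across specificity deciles
#'
#' Ordinary least squares of the per-decile liability R2 on the decile index
#' (1..10), adjusted for the number of SNPs in each decile score, with a
#' one-sided p-value for a positive slope (an increasing trend). A constant
#' SNP-count covariate is dropped automatically.
#'
#' @param decile_tbl Output of [decile_prs_r2()].
#' @return Tibble `slope`, `slope_se`, `statistic`, `p_trend`, `df`.
#' @export
decile_trend_test <- function(decile_tbl) {
  stopifnot(all(c("decile", "r2_liability", "n_snp") %in% names(decile_tbl)))
  dat <- decile_tbl
  use_nsnp <- length(unique(dat$n_snp)) > 1
  fml <- if (use_nsnp) r2_liability ~ decile + n_snp else r2_liability ~ decile
  fit <- lm(fml, data = dat)
  # perfect-fit warnings arise only for the degenerate profiles handled below
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- sm["decile", "Estimate"]
  se <- sm["decile", "Std. Error"]
  tval <- sm["decile", "t value"]
  df <- fit$df.residual
  # a numerically perfect fit (flat or exactly linear profile) leaves zero
  # residual variance; resolve the 0/0 by the size and sign of the slope
  if (!is.finite(tval) || se < 1e-10) {
    tval <- if (abs(est) < 1e-10) 0 else sign(est) * Inf
    est <- if (abs(est) < 1e-10) 0 else est
  }
  tibble(slope = est, slope_se = se, statistic = tval,
         p_trend = pt(tval, df = df, lower.tail = FALSE), df = df)
}

#' Two-phase cell-type polygenic-risk trend scan
#'
#' For each cell type: bin genes into specificity deciles, compute per-decile
#' polygenic R2 in the training and testing cohorts, and test the increasing
#' trend in each phase. A cell type is reported as replicated when the
#' one-sided trend p is below `alpha` in *both* phases.
#'
#' @param specificity Specificity tibble ([compute_specificity()]).
#' @param genes Gene annotation.
#' @param sumstats Reference summary statistics.
#' @param train_panel,train_pheno,test_panel,test_pheno The two cohorts.
#' @param alpha Per-phase significance level (default 0.05).
#' @param ... Passed to [decile_prs_r2()].
#' @return A `celltype_scan` tibble: one row per cell type and phase with
#'   the trend statistics plus a `replicated` flag; per-decile detail in the
#'   `deciles` attribute.
#' @export
scan_celltype_trend <- function(specificity, genes, sumstats,
                                train_panel, train_pheno,
                                test_panel, test_pheno,
                                alpha = 0.05, ...) {
  cts <- setdiff(names(specificity), "gene")
  detail <- list()
  rows <- purrr::map(cts, function(ct) {
    assignment <- assign_specificity_deciles(specificity, ct)
    per_phase <- purrr::imap(
      list(training = list(train_panel, train_pheno),
           testing = list(test_panel, test_pheno)),
      function(cohort, phase) {
        dec <- decile_prs_r2(assignment, genes, sumstats,
                             cohort[[1]], cohort[[2]], ...)
        trend <- decile_trend_test(dec)
        detail[[paste(ct, phase, sep = ".")]] <<- mutate(
          dec, cell_type = ct, phase = phase)
        mutate(trend, cell_type = ct, phase = phase)
      })
    both <- bind_rows(per_phase)
    both$replicated <- all(both$p_trend < alpha)
    both
  })
  out <- bind_rows(rows) %>%
    select("cell_type", "phase", "slope", "slope_se", "statistic",
           "p_trend", "df", "replicated")
  structure(out,
            class = c("celltype_scan", class(tibble())),
            deciles = bind_rows(detail))
}

#' @export
print.celltype_scan <- function(x, ...) {
  n_rep <- length(unique(x$cell_type[x$replicated]))
  cat(sprintf("Cell-type specificity-decile trend scan: %d cell types, %d replicated\n",
              length(unique(x$cell_type)), n_rep))
  NextMethod()
}
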