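#' Two-phase pathway polygenic-effect-score scan
#'
#' For every gene set: restrict the reference summary statistics to variants
#' inside member-gene bodies, apply the p/MAF pre-filter, LD-clump on the
#' cohort's dosages, compute the weighted allele-dose score, fit the logistic
#' association with covariates, and attach a label-permutation p-value and
#' the liability-scale Nagelkerke R2. Sets whose training empirical p falls
#' below the scan-wide Bonferroni line `alpha / n_sets` advance and are
#' re-evaluated identically on the testing cohort; a set is *replicated*
#' when it also passes that same line there. Both the scan-wide threshold
#' and the replication-stage threshold `alpha / n_advanced` are reported.
#'
#' Sets that end with zero usable variants are emitted with `n_snp = 0` and
#' still count in the Bonferroni denominator (the denominator is the number
#' of sets scanned).
#'
#' @param collection A `geneset_collection`.
#' @param variant_map Named list (set id -> variant ids), e.g. from
#'   [map_variants_to_sets()].
#' @param sumstats Reference summary statistics (`id`, `effect_allele`,
#'   `beta`, `se`, `p`, `freq`).
#' @param train_panel,train_pheno Training [genotype_panel()] and phenotype
#'   tibble (`sample_id`, `status`, covariates).
#' @param test_panel,test_pheno Testing cohort; omit for a single-phase scan.
#' @param p_max,maf_min Summary-statistic pre-filter (see
#'   [filter_summary_stats()]).
#' @param r2_max,window_bp Clumping parameters (see [ld_clump()]).
#' @param prevalence Population prevalence for the liability conversion.
#' @param n_pcs Number of principal-component covariates used.
#' @param n_perm Permutations per set.
#' @param alpha Family-wise error rate for the Bonferroni lines.
#' @param normalize Score normalization, `"mean"` or `"sum"`.
#' @param seed Scan seed; each set's permutation seed is derived from it by
#'   hashing the set id.
#' @return A `pes_scan` tibble: one row per set and phase with `set_id`,
#'   `phase`, `r2_liability`, `beta`, `se`, `p_empirical`, `n_snp`, and (for
#'   testing rows) `replicated`. Attribute `thresholds` records the exact
#'   Bonferroni lines used.
#' @export
scan_pathway_pes <- function(collection, variant_map, sumstats,
                             train_panel, train_pheno,
                             test_panel = NULL, test_pheno = NULL,
                             p_max = 0.05, maf_min = 0.01,
                             r2_max = 0.1, window_bp = 250000,
                             prevalence = 0.005, n_pcs = 20,
                             n_perm = 1000, alpha = 0.05,
                             normalize = "mean", seed = 1) {
  stopifnot(nrow(collection) >= 1)
  two_phase <- !is.null(test_panel)
  if (two_phase && length(intersect(train_pheno$sample_id,
                                    test_pheno$sample_id))) {
    abort("training and testing samples must be disjoint")
  }
  sumstats_f <- filter_summary_stats(sumstats, p_max, maf_min)
  covs <- default_covariates(train_pheno, n_pcs)
  n_sets <- nrow(collection)
  thr_scan <- bonferroni_threshold(alpha, n_sets)

  train_rows <- purrr::map(collection$set_id, function(sid) {
    pes_phase_row(
      set_id = sid, phase = "training",
      snp_ids = variant_map[[sid]] %||% character(),
      sumstats_f = sumstats_f, panel = train_panel, pheno = train_pheno,
      covariates = covs, prevalence = prevalence, n_perm = n_perm,
      seed = derive_seed(seed, sid), normalize = normalize,
      r2_max = r2_max, window_bp = window_bp
    )
  })
  out <- bind_rows(train_rows)
  advanced <- out$set_id[!is.na(out$p_empirical) & out$p_empirical < thr_scan]
  thr_repl <- if (length(advanced)) bonferroni_threshold(alpha, length(advanced)) else NA_real_

  if (two_phase && length(advanced)) {
    test_rows <- purrr::map(advanced, function(sid) {
      pes_phase_row(
        set_id = sid, phase = "testing",
        snp_ids = variant_map[[sid]] %||% character(),
        sumstats_f = sumstats_f, panel = test_panel, pheno = test_pheno,
        covariates = covs, prevalence = prevalence, n_perm = n_perm,
        seed = derive_seed(seed + 1L, sid), normalize = normalize,
        r2_max = r2_max, window_bp = window_bp
      )
    })
    test_tbl <- bind_rows(test_rows) %>%
      mutate(replicated = !is.na(.data$p_empirical) &
               .data$p_empirical < thr_scan)
    out <- bind_rows(mutate(out, replicated = NA), test_tbl)
  } else {
    out <- mutate(out, replicated = NA)
  }
  structure(out,
            class = c("pes_scan", class(tibble())),
            thresholds = list(
              alpha = alpha, n_sets = n_sets,
              scan = thr_scan,
              n_advanced = length(advanced),
              replication = thr_repl
            ),
            advanced = advanced)
}

# One (set, cohort) evaluation: clump -> score -> fit -> permute.
pes_phase_row <- function(set_id, phase, snp_ids, sumstats_f, panel, pheno,
                          covariates, prevalence, n_perm, seed, normalize,
                          r2_max, window_bp) {
  empty <- tibble(set_id = set_id, phase = phase,
                  r2_liability = NA_real_, beta = NA_real_, se = NA_real_,
                  p_empirical = NA_real_, n_snp = 0L)
  cand <- sumstats_f[sumstats_f$id %in% snp_ids &
                       sumstats_f$id %in% colnames(panel$dosage), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  res <- tryCatch({
    idx <- ld_clump(cand, panel, r2_max = r2_max, window_bp = window_bp)
    sc <- compute_pes(panel, sumstats_f, idx, normalize = normalize)
    fit <- fit_pes_association(pheno, sc, covariates)
    perm <- permutation_pvalue(pheno, sc, covariates,
                               n_perm = n_perm, seed = seed)
    P <- mean(pheno$status[pheno$sample_id %in%
                             sc$sample_id[!is.na(sc$score)]])
    tibble(
      set_id = set_id, phase = phase,
      r2_liability = liability_r2(min(fit$r2_nagelkerke, 1), prevalence, P),
      beta = fit$beta, se = fit$se,
      p_empirical = perm$p_empirical, n_snp = length(idx)
    )
  }, error = function(e) empty)
  res
}

#' @export
print.pes_scan <- function(x, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "Pathway PES scan: %d sets, Bonferroni %.3g (scan), %.3g (replication, %d advanced)\n",
    thr$n_sets, thr$scan, thr$replication, thr$n_advanced
  ))
  NextMethod()
}

#' Significance thresholds applied by a scan
#'
#' @param scan A `pes_scan` (or `burden_scan`) object.
#' @return Tibble of the Bonferroni lines actually used.
#' @export
scan_thresholds <- function(scan) {
  thr <- attr(scan, "thresholds")
  tibble(
    stage = c("scan", "replication"),
    alpha = thr$alpha,
    n_tests = c(thr$n_sets, thr$n_advanced),
    threshold = c(thr$scan, thr$replication)
  )
}
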