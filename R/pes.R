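#' Filter GWAS summary statistics for score construction
#'
#' Keeps variants with association `p <= p_max` (inclusive) and minor allele
#' frequency strictly greater than `maf_min`, the pre-filter applied before
#' LD clumping. MAF is derived from the effect-allele frequency column.
#'
#' @param sumstats Tibble with at least `id`, `p`, `freq`.
#' @param p_max Inclusive p-value ceiling (default 0.05).
#' @param maf_min Exclusive MAF floor (default 0.01).
#' @return The filtered summary-statistics tibble.
#' @export
filter_summary_stats <- function(sumstats, p_max = 0.05, maf_min = 0.01) {
  maf <- pmin(sumstats$freq, 1 - sumstats$freq)
  sumstats[sumstats$p <= p_max & maf > maf_min, , drop = FALSE]
}

#' A genotype panel: additive dosages plus the variant table
#'
#' @param dosage Numeric matrix, samples x variants, entries in `[0, 2]`
#'   (dosage of the counted allele `a1`); `NA` allowed. Row names are sample
#'   ids, column names variant ids.
#' @param variants Tibble `id`, `chrom`, `pos`, `a1`, `a2`, `maf` describing
#'   the columns (`a1` is the counted allele).
#' @return A validated `genotype_panel` list.
#' @export
genotype_panel <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)),
            !is.null(rownames(dosage)))
  if (!all(colnames(dosage) %in% variants$id)) {
    abort("every dosage column must be described in the variant table")
  }
  variants <- variants[match(colnames(dosage), variants$id), , drop = FALSE]
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, variants = as_tibble(variants)),
            class = "genotype_panel")
}

#' Greedy LD clumping of candidate variants
#'
#' Standard index-variant clumping: repeatedly take the remaining candidate
#' with the smallest p-value as an index and discard all remaining candidates
#' on the same chromosome within `window_bp` whose squared dosage correlation
#' with the index is at least `r2_max`. Ties in p are broken by (chrom, pos).
#'
#' @param candidates Summary-statistics tibble (`id`, `p`) restricted to the
#'   variants under consideration.
#' @param panel A [genotype_panel()] supplying dosages and coordinates; the
#'   clumping r2 is computed on these dosages.
#' @param r2_max Squared-correlation threshold (default 0.1).
#' @param window_bp Clumping distance (default 250 kb).
#' @return Character vector of retained index-variant ids.
#' @export
ld_clump <- function(candidates, panel, r2_max = 0.1, window_bp = 250000) {
  stopifnot(r2_max > 0, r2_max < 1, window_bp > 0)
  missing_ids <- setdiff(candidates$id, colnames(panel$dosage))
  if (length(missing_ids)) {
    abort(sprintf("variant(s) absent from genotype panel: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  info <- panel$variants[match(candidates$id, panel$variants$id), ]
  ord <- order(candidates$p, info$chrom, info$pos)
  id <- candidates$id[ord]
  chrom <- info$chrom[ord]
  pos <- info$pos[ord]
  alive <- rep(TRUE, length(id))
  keep <- character(0)
  for (i in seq_along(id)) {
    if (!alive[i]) next
    keep <- c(keep, id[i])
    alive[i] <- FALSE
    near <- which(alive & chrom == chrom[i] & abs(pos - pos[i]) <= window_bp)
    if (length(near)) {
      r <- suppressWarnings(cor(panel$dosage[, id[i]],
                                panel$dosage[, id[near], drop = FALSE],
                                use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      r2[!is.finite(r2)] <- 0
      alive[near[r2 >= r2_max]] <- FALSE
    }
  }
  keep
}

#' Polygenic effect score from weighted allele doses
#'
#' `score_i = sum_j beta_j * dose_ij / m_i`, where `dose_ij` counts the
#' effect allele and `m_i` is the number of non-missing variants for sample
#' `i` (missing dosages drop out of both sums). Weights whose effect allele
#' is the panel's other allele are applied to the flipped dose `2 - d`, so
#' the score does not depend on which allele the panel happens to count.
#'
#' @param panel A [genotype_panel()].
#' @param weights Summary-statistics tibble with `id`, `effect_allele`,
#'   `beta`.
#' @param snp_ids Variant ids entering the score (nonempty).
#' @param normalize `"mean"` (per-SNP average, the default) or `"sum"` (raw
#'   weighted sum).
#' @return Tibble `sample_id`, `score`, `n_snp_used`; samples with every
#'   dosage missing get `NA` score and are flagged via the `dropped`
#'   attribute.
#' @export
compute_pes <- function(panel, weights, snp_ids,
                        normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  if (length(snp_ids) == 0L) abort("snp_ids must be nonempty")
  w <- weights[match(snp_ids, weights$id), , drop = FALSE]
  if (anyNA(w$id)) abort("snp_ids missing from the weights table")
  v <- panel$variants[match(snp_ids, panel$variants$id), , drop = FALSE]
  if (anyNA(v$id)) abort("snp_ids missing from the genotype panel")
  match_a1 <- w$effect_allele == v$a1
  match_a2 <- w$effect_allele == v$a2
  if (any(!match_a1 & !match_a2)) {
    abort(sprintf("effect allele matches neither panel allele for: %s",
                  paste(snp_ids[!match_a1 & !match_a2], collapse = ", ")))
  }
  D <- panel$dosage[, snp_ids, drop = FALSE]
  D[, match_a2] <- 2 - D[, match_a2, drop = FALSE]
  obs <- !is.na(D)
  D[!obs] <- 0
  num <- as.numeric(D %*% w$beta)
  m <- unname(rowSums(obs))
  score <- if (normalize == "mean") num / m else num
  score <- unname(score)
  score[m == 0] <- NA_real_
  out <- tibble(sample_id = rownames(panel$dosage),
                score = score, n_snp_used = as.integer(m))
  attr(out, "dropped") <- out$sample_id[m == 0]
  out
}

#' Logistic association of a polygenic score with case status
#'
#' Fits `status ~ standardized score + covariates` by maximum-likelihood
#' logistic regression and reports the Wald statistics for the score term
#' together with Nagelkerke's pseudo-R2 computed from the full versus
#' covariate-only likelihoods:
#' `R2_N = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))`.
#'
#' @param phenotype Tibble with `status` (0 control / 1 case) and numeric
#'   covariate columns; if `score` is a tibble from [compute_pes()] it is
#'   joined on `sample_id`, otherwise it must be a vector aligned with the
#'   phenotype rows.
#' @param score Numeric score vector or [compute_pes()] output.
#' @param covariates Character vector of covariate column names (default:
#'   every column except `sample_id`/`status`).
#' @param n_pcs Cap on the number of `PC*` columns used (default all).
#' @return An object of class `pes_fit` with elements `beta`, `se`, `z`,
#'   `p_wald`, `r2_nagelkerke`, `n`, `n_case`, `separated`, and the design
#'   kept for permutation reuse. `tidy()`/`glance()` methods are available.
#' @export
fit_pes_association <- function(phenotype, score,
                                covariates = default_covariates(phenotype, n_pcs),
                                n_pcs = Inf) {
  score <- align_score(phenotype, score)
  keep <- !is.na(score)
  phenotype <- phenotype[keep, , drop = FALSE]
  score <- score[keep]
  d <- build_design(phenotype, score, covariates)
  full <- logistic_fit(d$X, d$y)
  nullm <- logistic_fit(d$X[, -ncol(d$X), drop = FALSE], d$y)
  n <- length(d$y)
  r2 <- nagelkerke_r2(nullm$loglik, full$loglik, n)
  k <- ncol(d$X)
  z <- full$coef[k] / full$se[k]
  structure(list(
    beta = unname(full$coef[k]), se = unname(full$se[k]), z = unname(z),
    p_wald = if (full$separated) NA_real_ else
      unname(2 * pnorm(abs(z), lower.tail = FALSE)),
    r2_nagelkerke = r2,
    loglik_full = full$loglik, loglik_null = nullm$loglik,
    n = n, n_case = sum(d$y), separated = full$separated,
    design = d, covariates = covariates
  ), class = "pes_fit")
}

align_score <- function(phenotype, score) {
  if (is.data.frame(score)) {
    idx <- match(phenotype$sample_id, score$sample_id)
    if (anyNA(idx)) abort("score table does not cover all phenotype samples")
    score$score[idx]
  } else {
    as.numeric(score)
  }
}

nagelkerke_r2 <- function(ll0, ll1, n) {
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  max_r2 <- 1 - exp(2 * ll0 / n)
  if (max_r2 <= 0) return(0)
  max(cox_snell / max_r2, 0)
}

#' @export
print.pes_fit <- function(x, ...) {
  cat("Polygenic-score logistic association\n")
  cat(sprintf("  n = %d (%d cases), beta = %.4f (se %.4f), Wald p = %.3g\n",
              x$n, x$n_case, x$beta, x$se, x$p_wald))
  cat(sprintf("  Nagelkerke R2 = %.5f%s\n", x$r2_nagelkerke,
              if (x$separated) "  [flagged: separation]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pes_fit <- function(x, ...) {
  tibble(term = "score", estimate = x$beta, std.error = x$se,
         statistic = x$z, p.value = x$p_wald)
}

#' @export
glance.pes_fit <- function(x, ...) {
  tibble(r2_nagelkerke = x$r2_nagelkerke, logLik = x$loglik_full,
         logLik_null = x$loglik_null, nobs = x$n, n_case = x$n_case,
         separated = x$separated)
}

#' Convert an observed Nagelkerke R2 to the liability scale
#'
#' Lee et al. (2012) transformation for ascertained case-control samples:
#' given population prevalence `K` and sample case proportion `P`,
#' `t = qnorm(1 - K)`, `z = dnorm(t)`, `m = z / K`,
#' `C = K(1-K)/z^2 * K(1-K)/(P(1-P))`,
#' `theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t)`, and
#' `r2_liab = C r2 / (1 + C theta r2)`.
#'
#' @param r2_obs Observed-scale R2 in `[0, 1]`.
#' @param K Population prevalence (default 0.005, an aged-population
#'   Parkinson-disease estimate).
#' @param P Sample case proportion.
#' @return Liability-scale R2.
#' @export
liability_r2 <- function(r2_obs, K = 0.005, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) {
    abort("K and P must lie strictly within (0, 1)")
  }
  stopifnot(all(r2_obs >= 0), all(r2_obs <= 1))
  t <- qnorm(1 - K)
  z <- dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  C * r2_obs / (1 + C * theta * r2_obs)
}

#' Permutation p-value for a score-phenotype association
#'
#' Permutes the case/control labels (covariates stay attached to their
#' samples), refits the logistic model each time, and compares the absolute
#' Wald z of the score term against the observed one:
#' `p = (1 + #\{|z_perm| >= |z_obs|\}) / (n_perm + 1)`.
#'
#' @inheritParams fit_pes_association
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `p_empirical`, `z_obs`, `n_perm`.
#' @export
permutation_pvalue <- function(phenotype, score,
                               covariates = default_covariates(phenotype),
                               n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  score <- align_score(phenotype, score)
  keep <- !is.na(score)
  d <- build_design(phenotype[keep, , drop = FALSE], score[keep], covariates)
  z_obs <- wald_z_last(d$X, d$y)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z_perm <- vapply(seq_len(n_perm), function(b) {
    wald_z_last(d$X, sample(d$y))
  }, numeric(1))
  list(
    p_empirical = (1 + sum(z_perm >= z_obs)) / (n_perm + 1),
    z_obs = z_obs, n_perm = n_perm
  )
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Deterministic 31-bit seed for a set id, derived from the scan seed.
derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + seed) %% 2147483647)
}
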