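#' Default rho grid for SKAT-O
#'
#' The standard mixing grid `{0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1}`
#' spanning pure SKAT (`rho = 0`) to the pure weighted burden test
#' (`rho = 1`).
#' @return Numeric vector of rho values.
#' @export
skat_rho_grid <- function() c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)

#' SKAT-O: optimal unified rare-variant association test
#'
#' Score-based variance-component test for a set of rare variants against a
#' binary phenotype. The null model is the covariates-only logistic
#' regression; each variant gets weight `dbeta(maf, weights_beta[1],
#' weights_beta[2])` (default Beta(1, 25), up-weighting rarer alleles); the
#' family statistic is `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` on the
#' weighted score residuals, and the reported p-value is the optimal test
#' over the `rho` grid via the one-dimensional chi-square integration of the
#' unified-test construction, with quadratic-form tails from exact
#' characteristic-function inversion ([quadform_pvalue()]).
#'
#' With a single-element grid the corresponding component test is returned
#' exactly: `rho = 0` is plain SKAT and `rho = 1` the weighted burden score
#' test.
#'
#' @param genotypes Numeric dosage matrix, samples x variants; missing
#'   entries are mean-imputed per variant.
#' @param phenotype Tibble with binary `status` and covariate columns.
#' @param covariates Covariate column names for the null model.
#' @param rho Mixing grid in `[0, 1]`.
#' @param weights_beta Beta-density parameters for the MAF weights.
#' @param weights Optional explicit per-variant weights (overrides
#'   `weights_beta`).
#' @param maf Optional per-variant MAFs; computed from the dosages (combined
#'   case + control panel) when omitted.
#' @return Object of class `skat_o`: `p` (the SKAT-O p-value), `p_rho`
#'   (per-rho component p-values), `n_snp`, `min_p`, and `method`.
#' @export
skat_o <- function(genotypes, phenotype,
                   covariates = default_covariates(phenotype),
                   rho = skat_rho_grid(), weights_beta = c(1, 25),
                   weights = NULL, maf = NULL) {
  G <- as.matrix(genotypes)
  m <- ncol(G)
  stopifnot(m >= 1, all(rho >= 0), all(rho <= 1))
  y <- phenotype$status
  if (!all(y %in% c(0, 1))) abort("status must be binary 0/1")
  # mean-impute missing dosages per variant
  if (anyNA(G)) {
    mu_col <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu_col[idx[, 2]]
  }
  if (is.null(maf)) {
    f <- colMeans(G) / 2
    maf <- pmin(f, 1 - f)
  }
  if (is.null(weights)) weights <- dbeta(maf, weights_beta[1], weights_beta[2])

  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (length(covariates))
               as.matrix(phenotype[, covariates, drop = FALSE]))
  nullfit <- logistic_fit(X, y)
  mu <- nullfit$fitted
  v <- mu * (1 - mu)
  qrX <- qr(X * sqrt(v))
  if (qrX$rank < ncol(X)) abort("singular null-model design")

  Gw <- sweep(G, 2, weights, `*`)
  s <- as.numeric(crossprod(Gw, y - mu))
  VX <- X * v
  A <- crossprod(Gw, VX)
  B <- crossprod(X, VX)
  Sigma <- crossprod(Gw, Gw * v) - A %*% solve(B, t(A))
  Sigma <- (Sigma + t(Sigma)) / 2

  q_skat <- sum(s^2)
  q_burden <- sum(s)^2
  q_rho <- (1 - rho) * q_skat + rho * q_burden

  lambda_rho <- purrr::map(rho, function(r) {
    Rh <- rho_half_matrix(r, m)
    eigen(Rh %*% Sigma %*% Rh, symmetric = TRUE, only.values = TRUE)$values
  })
  p_rho <- purrr::map2_dbl(q_rho, lambda_rho,
                           function(q, l) as.numeric(quadform_pvalue(q, l)))
  comp <- tibble(rho = rho, q = q_rho, p = p_rho)

  if (length(rho) == 1L) {
    return(structure(list(p = p_rho[[1]], p_rho = comp, n_snp = m,
                          min_p = p_rho[[1]], method = "component"),
                     class = "skat_o"))
  }
  t_min <- min(p_rho)
  p_opt <- tryCatch(
    skat_o_omnibus(t_min, Sigma, rho, lambda_rho, m),
    error = function(e) NA_real_
  )
  method <- "omnibus"
  if (!is.finite(p_opt) || p_opt <= 0) {
    p_opt <- min(t_min * length(rho), 1)  # Bonferroni over the grid
    method <- "bonferroni-fallback"
  }
  structure(list(p = min(p_opt, 1), p_rho = comp, n_snp = m,
                 min_p = t_min, method = method),
            class = "skat_o")
}

# Symmetric square root of R_rho = (1 - rho) I + rho 11'.
rho_half_matrix <- function(r, m) {
  a <- sqrt(1 - r)
  b <- (sqrt(1 - r + m * r) - a) / m
  out <- matrix(b, m, m)
  diag(out) <- a + b
  out
}

# P(min_rho p_rho <= t_min) via the mixture representation
# Q_rho = (1 - rho) kappa + tau(rho) eta0, eta0 ~ chi2_1.
skat_o_omnibus <- function(t_min, Sigma, rho, lambda_rho, m) {
  rho_adj <- pmin(rho, 0.999)
  one <- rep(1, m)
  sig1 <- as.numeric(Sigma %*% one)
  zbar2 <- sum(sig1) / m^2            # ||z_bar||^2
  if (zbar2 <= 0) abort("degenerate burden direction")
  cof1 <- (sig1 / m) / zbar2
  zt <- Sigma - cof1 %*% t(sig1 / m) - (sig1 / m) %*% t(cof1) +
    (cof1 %*% t(cof1)) * zbar2
  lambda_t <- clean_lambda(eigen((zt + t(zt)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values)
  var_remain <- 4 * zbar2 * as.numeric(t(cof1) %*% zt %*% cof1)
  mu_q <- sum(lambda_t)
  var_q <- 2 * sum(lambda_t^2) + var_remain
  tau <- (m^2 * rho_adj + (1 - rho_adj) * sum(cof1^2)) * zbar2
  q_min <- purrr::map_dbl(lambda_rho,
                          function(l) liu_quantile(t_min, clean_lambda(l)))
  sd_ratio <- sqrt(max(var_q - var_remain, 0) / var_q)

  kappa_cdf <- function(t) {
    if (t <= 0) return(0)
    tq <- (t - mu_q) * sd_ratio + mu_q
    if (tq <= 0) return(0)
    1 - as.numeric(quadform_pvalue(tq, lambda_t))
  }
  # integrate over eta0 = x ~ chi2_1 with x = u^2 (integrand smooth in u)
  gq <- gauss_legendre(48, 0, 8)
  fvals <- vapply(gq$x, function(u) {
    x <- u^2
    tmin <- min((q_min - tau * x) / (1 - rho_adj))
    kappa_cdf(tmin) * 2 * dnorm(u)
  }, numeric(1))
  1 - sum(gq$w * fvals)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch).
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (a + b) / 2 + (b - a) / 2 * e$values,
       w = (b - a) / 2 * 2 * e$vectors[1, ]^2)
}

#' @export
print.skat_o <- function(x, ...) {
  cat(sprintf("SKAT-O: p = %.4g over %d variants (%s; min component p %.4g)\n",
              x$p, x$n_snp, x$method, x$min_p))
  invisible(x)
}

#' @export
tidy.skat_o <- function(x, ...) x$p_rho

#' @export
glance.skat_o <- function(x, ...) {
  tibble(p = x$p, n_snp = x$n_snp, min_component_p = x$min_p,
         method = x$method)
}

#' Select rare variants for one burden mask
#'
#' Restricts an annotated rare-variant table (long format: one row per
#' variant x functional category) to members of a gene set, one functional
#' category, `maf <= maf_max` (inclusive) and `mac >= mac_min`.
#'
#' @param variants Tibble `id`, `chrom`, `pos`, `gene`, `category`, `mac`,
#'   `maf`.
#' @param set_genes Member gene symbols.
#' @param category One of the annotation categories (e.g. `"missense"`,
#'   `"lof"`, `"cadd_gt12"`).
#' @param maf_max Frequency ceiling (0.03 or 0.01 in the standard masks).
#' @param mac_min Minor-allele-count floor (default 3).
#' @return The qualifying variant rows (possibly empty).
#' @export
build_burden_mask <- function(variants, set_genes, category,
                              maf_max, mac_min = 3) {
  stopifnot(maf_max > 0, maf_max <= 0.5)
  variants[variants$gene %in% set_genes &
             variants$category == category &
             variants$maf <= maf_max &
             variants$mac >= mac_min, , drop = FALSE]
}

#' Default burden masks: 3 functional categories x 2 MAF ceilings
#' @return Tibble `category`, `maf_max`.
#' @export
burden_masks <- function() {
  tidyr::expand_grid(category = c("missense", "lof", "cadd_gt12"),
                     maf_max = c(0.03, 0.01))
}

#' Gene-set rare-variant burden scan (SKAT-O)
#'
#' One SKAT-O test per (gene set, functional category, MAF ceiling). Empty
#' masks are emitted as `NA` rows. Alongside the nominal 0.05 line the scan
#' reports the per-scan Bonferroni threshold `alpha / n_sets`.
#'
#' @param collection A `geneset_collection`.
#' @param rare_variants Annotated variant table (see [build_burden_mask()]).
#' @param panel A [genotype_panel()] holding the rare-variant dosages.
#' @param phenotype Phenotype tibble (`status` + covariates).
#' @param masks Tibble `category`, `maf_max` (default [burden_masks()]).
#' @param covariates Covariate columns for the null model.
#' @param mac_min Minor-allele-count floor.
#' @param alpha Family-wise error rate for the reported threshold.
#' @return A `burden_scan` tibble: `set_id`, `category`, `maf_max`, `n_snp`,
#'   `p`, with a `thresholds` attribute.
#' @export
scan_burden <- function(collection, rare_variants, panel, phenotype,
                        masks = burden_masks(),
                        covariates = default_covariates(phenotype),
                        mac_min = 3, alpha = 0.05) {
  n_sets <- nrow(collection)
  rows <- purrr::pmap(
    tidyr::expand_grid(i = seq_len(max(n_sets, 0)),
                       j = seq_len(nrow(masks))),
    function(i, j) {
      sid <- collection$set_id[[i]]
      sub <- build_burden_mask(rare_variants, collection$genes[[i]],
                               masks$category[[j]], masks$maf_max[[j]],
                               mac_min)
      ids <- intersect(unique(sub$id), colnames(panel$dosage))
      if (length(ids) == 0L) {
        return(tibble(set_id = sid, category = masks$category[[j]],
                      maf_max = masks$maf_max[[j]], n_snp = NA_integer_,
                      p = NA_real_))
      }
      fit <- skat_o(panel$dosage[, ids, drop = FALSE], phenotype,
                    covariates = covariates)
      tibble(set_id = sid, category = masks$category[[j]],
             maf_max = masks$maf_max[[j]], n_snp = length(ids), p = fit$p)
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(set_id = character(), category = character(),
                  maf_max = numeric(), n_snp = integer(), p = numeric())
  }
  structure(out,
            class = c("burden_scan", class(tibble())),
            thresholds = list(alpha = alpha, n_sets = n_sets,
                              nominal = alpha,
                              scan = if (n_sets >= 1)
                                bonferroni_threshold(alpha, n_sets)
                              else NA_real_,
                              n_advanced = NA_integer_,
                              replication = NA_real_))
}

#' One singleton gene set per gene (for gene-level burden scans)
#'
#' @param genes Character vector of gene symbols.
#' @return A `geneset_collection` whose sets each contain a single gene,
#'   suitable for passing to [scan_burden()] for per-gene SKAT-O.
#' @export
singleton_collection <- function(genes) {
  genes <- unique(genes)
  new_geneset_collection(tibble(
    set_id = genes, source = "GENE",
    n_genes = 1L, genes = as.list(genes)
  ))
}
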