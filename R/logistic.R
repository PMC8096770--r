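# Internal logistic-regression workhorse.  The permutation layer refits the
# same design thousands of times, so this wraps glm.fit directly instead of
# the glm() formula interface.

logistic_fit <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  w <- fit$weights
  xtwx <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, ncol(X)) else sqrt(diag(vc))
  eps <- 1e-12
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  separated <- !fit$converged || fit$boundary ||
    any(!is.finite(se)) || max(abs(fit$coefficients), na.rm = TRUE) > 25
  list(
    coef = fit$coefficients, se = se, loglik = loglik,
    fitted = mu, converged = fit$converged, separated = separated
  )
}

# |Wald z| of the last design column (the score term).
wald_z_last <- function(X, y) {
  f <- logistic_fit(X, y)
  k <- ncol(X)
  z <- f$coef[k] / f$se[k]
  if (!is.finite(z)) z <- 0
  abs(z)
}

# Assemble [intercept | covariates | standardized score] from a phenotype
# table.  `covariates` are column names of `phenotype`.
build_design <- function(phenotype, score, covariates) {
  stopifnot(length(score) == nrow(phenotype))
  if (sd(score) == 0) abort("score has zero variance")
  covs <- if (length(covariates)) {
    as.matrix(phenotype[, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(phenotype), ncol = 0)
  }
  if (length(covs) && !all(is.finite(covs))) {
    abort("covariates must be numeric and finite")
  }
  X <- cbind(`(Intercept)` = 1, covs, score = as.numeric(scale(score)))
  y <- phenotype$status
  if (!all(y %in% c(0, 1))) abort("status must be binary 0/1")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("need at least 2 cases and 2 controls")
  }
  list(X = X, y = y)
}

# Default covariate set: every numeric column except ids/status.
default_covariates <- function(phenotype, n_pcs = Inf) {
  nm <- setdiff(names(phenotype), c("sample_id", "status"))
  pcs <- grep("^PC[0-9]+$", nm, value = TRUE)
  if (is.finite(n_pcs)) {
    keep_pcs <- paste0("PC", seq_len(min(n_pcs, length(pcs))))
    nm <- c(setdiff(nm, pcs), intersect(pcs, keep_pcs))
  }
  nm
}
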