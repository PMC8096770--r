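# Readers/writers for the plain-text interchange formats.  Columns follow
# the conventions stated in each reader; all return tibbles.

#' Read GWAS summary statistics
#'
#' Tab-delimited with header
#' `id effect_allele other_allele beta se p freq`.
#'
#' @param path File path.
#' @return Summary-statistics tibble.
#' @export
read_summary_stats <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "effect_allele", "other_allele", "beta", "se", "p", "freq")
  if (!all(need %in% names(out))) {
    abort(sprintf("summary statistics must have columns: %s",
                  paste(need, collapse = " ")))
  }
  if (any(out$se <= 0) || any(out$p <= 0 | out$p > 1)) {
    abort("summary statistics: need se > 0 and p in (0, 1]")
  }
  out
}

#' Read a variant table
#'
#' TSV with header `id chrom pos a1 a2 maf` (1-based positions, `a1` the
#' counted allele). Ids must be unique and `maf <= 0.5`.
#'
#' @param path File path.
#' @return Variant tibble.
#' @export
read_variant_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "chrom", "pos", "a1", "a2", "maf")
  if (!all(need %in% names(out))) {
    abort(sprintf("variant table must have columns: %s",
                  paste(need, collapse = " ")))
  }
  if (anyDuplicated(out$id)) abort("variant ids must be unique")
  if (any(out$maf > 0.5 | out$maf <= 0)) abort("maf must lie in (0, 0.5]")
  out
}

#' Read an additive-dosage matrix
#'
#' TSV whose first column is `sample_id` and remaining columns are variant
#' ids holding dosages in `[0, 2]` (NA allowed).
#'
#' @param path File path.
#' @param variants Variant tibble describing the columns.
#' @return A [genotype_panel()].
#' @export
read_dosage_tsv <- function(path, variants) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl[[1]]
  genotype_panel(mat, variants)
}

#' Read genotypes from a VCF into a dosage panel
#'
#' Uses the DS FORMAT field when present, otherwise additive-codes GT.
#' The counted allele is ALT.
#'
#' @param path Path to a (optionally gzipped) VCF.
#' @return A [genotype_panel()]; MAF is computed from the dosages.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- "DS" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  mat <- if (has_ds) {
    apply(vcfR::extract.gt(v, element = "DS"), c(1, 2), as.numeric)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.numeric(strsplit(x, "[/|]")[[1]]))
    })
  }
  dosage <- t(mat)  # samples x variants
  colnames(dosage) <- fix[, "ID"]
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants <- tibble(
    id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]),
    a1 = fix[, "ALT"], a2 = fix[, "REF"],
    maf = pmin(freq, 1 - freq)
  )
  genotype_panel(dosage, variants)
}

#' Read a phenotype/covariate table
#'
#' TSV with `sample_id`, binary `status`, and numeric covariates (age, sex,
#' `PC1..PCk`).
#'
#' @param path File path.
#' @return Phenotype tibble.
#' @export
read_phenotype_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "status") %in% names(out))) {
    abort("phenotype table needs sample_id and status columns")
  }
  if (!all(out$status %in% c(0, 1))) abort("status must be binary 0/1")
  out
}

#' Read a genes-x-cell-types expression or specificity matrix
#'
#' TSV whose first column is `gene` and remaining columns are cell types.
#'
#' @param path File path.
#' @return Tibble `gene` + one column per cell type.
#' @export
read_celltype_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene"
  out
}

#' Read cis-eQTL summary statistics
#'
#' TSV with header `gene snp b_eqtl se_eqtl p_eqtl` and optional `tissue`.
#'
#' @param path File path.
#' @return eQTL tibble.
#' @export
read_eqtl_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "snp", "b_eqtl", "se_eqtl", "p_eqtl")
  if (!all(need %in% names(out))) {
    abort(sprintf("eQTL table must have columns: %s",
                  paste(need, collapse = " ")))
  }
  out
}

#' Read a square LD matrix keyed by SNP id
#'
#' TSV with a `snp` first column and one column per SNP (signed r).
#'
#' @param path File path.
#' @return Symmetric matrix with unit diagonal.
#' @export
read_ld_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(mat) <- tbl[[1]]
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-8))) {
    abort("LD matrix must be symmetric")
  }
  if (!isTRUE(all.equal(unname(diag(mat)), rep(1, nrow(mat)),
                        tolerance = 1e-8))) {
    abort("LD matrix must have unit diagonal")
  }
  mat
}

# Write a tibble as TSV (used by the pipeline stage outputs).
write_stage_tsv <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}
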