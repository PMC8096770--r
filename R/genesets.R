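#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT dialect used by MSigDB (one gene set per line:
#' set id, description, then member genes). Duplicate genes within a line are
#' collapsed, and the annotation source (REACTOME, KEGG, BIOCARTA, PID, ...)
#' is inferred from the set-id prefix, falling back to the description field
#' and finally to `"OTHER"`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with class `geneset_collection`: one row per gene set with
#'   columns `set_id`, `source`, `n_genes` and a list-column `genes` of unique
#'   gene symbols.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("KEGG_LYSOSOME\tna\tGBA\tLAMP1", "REACTOME_X\tna\tSNCA"), gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_geneset_collection(tibble(
      set_id = character(), source = character(),
      n_genes = integer(), genes = list()
    )))
  }
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      abort(sprintf("malformed GMT line %d: fewer than 2 tab-separated fields", i))
    }
    set_id <- trimws(fields[[1]])
    if (!nzchar(set_id)) {
      abort(sprintf("malformed GMT line %d: empty set id", i))
    }
    genes <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    tibble(
      set_id = set_id,
      source = infer_set_source(set_id, fields[[2]]),
      n_genes = length(genes),
      genes = list(genes)
    )
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out$set_id)) {
    abort(sprintf(
      "duplicated set id(s) in GMT: %s",
      paste(unique(out$set_id[duplicated(out$set_id)]), collapse = ", ")
    ))
  }
  new_geneset_collection(out)
}

new_geneset_collection <- function(tbl) {
  structure(tbl, class = c("geneset_collection", class(tibble())))
}

# Known MSigDB "Canonical Pathways" prefixes.  Unrecognized -> OTHER, never fatal.
.known_sources <- c(
  "REACTOME", "KEGG", "BIOCARTA", "PID", "NABA", "SIG", "SA", "ST", "WP"
)

infer_set_source <- function(set_id, description = "") {
  prefix <- toupper(strsplit(set_id, "_", fixed = TRUE)[[1]][1])
  if (prefix %in% .known_sources) return(prefix)
  desc <- toupper(trimws(description))
  if (desc %in% .known_sources) return(desc)
  "OTHER"
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]: one line per set, source written in the
#' description field so that a round trip preserves the collection.
#'
#' @param collection A `geneset_collection` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$set_id, collection$source, collection$genes),
    function(id, src, genes) paste(c(id, src, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Per-source gene-set counts
#'
#' @param collection A `geneset_collection`.
#' @return Tibble with `source` and `n_sets`; `sum(n_sets)` always equals the
#'   number of sets in the collection.
#' @export
count_sets_by_source <- function(collection) {
  collection %>%
    as_tibble() %>%
    count(.data$source, name = "n_sets") %>%
    arrange(desc(.data$n_sets), .data$source)
}

#' Read gene coordinates from a BED4 file
#'
#' Expects chrom, start, end, name (gene symbol); BED convention, i.e.
#' 0-based half-open intervals. Duplicate symbols are rejected.
#'
#' @param path Path to a 4-column BED file (no header).
#' @return Tibble `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "symbol"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), symbol = readr::col_character()
    ),
    progress = FALSE
  )
  validate_gene_table(tbl[, c("symbol", "chrom", "start", "end")])
}

validate_gene_table <- function(genes) {
  genes <- as_tibble(genes)
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start >= genes$end)) {
    abort("gene annotation: every interval must satisfy start < end")
  }
  if (anyDuplicated(genes$symbol)) {
    abort(sprintf(
      "gene annotation: duplicated symbol(s): %s",
      paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", ")
    ))
  }
  genes
}

#' Map variants into the gene bodies of one gene set
#'
#' A variant belongs to a set when its position falls inside any member
#' gene's `[start, end)` interval — gene bodies only, no flanking windows,
#' so regulatory regions up/downstream are deliberately not covered.
#'
#' @param variants Tibble with `id`, `chrom`, `pos` (1-based).
#' @param genes Gene annotation tibble (`symbol`, `chrom`, `start`, `end`).
#' @param set_genes Character vector of member gene symbols.
#' @return List with `variant_ids` (deduplicated, in variant-table order) and
#'   `n_skipped_genes` (member genes absent from the annotation).
#' @export
map_variants_to_gene_set <- function(variants, genes, set_genes) {
  set_genes <- unique(set_genes)
  ann <- genes[genes$symbol %in% set_genes, , drop = FALSE]
  n_skipped <- length(set_genes) - nrow(ann)
  if (nrow(ann) == 0L) {
    return(list(variant_ids = character(), n_skipped_genes = n_skipped))
  }
  hit <- rep(FALSE, nrow(variants))
  for (chr in unique(ann$chrom)) {
    g <- ann[ann$chrom == chr, , drop = FALSE]
    vi <- which(variants$chrom == chr)
    if (length(vi) == 0L) next
    pos <- variants$pos[vi]
    for (k in seq_len(nrow(g))) {
      hit[vi[pos >= g$start[k] & pos < g$end[k]]] <- TRUE
    }
  }
  list(
    variant_ids = unique(variants$id[hit]),
    n_skipped_genes = n_skipped
  )
}

#' Map variants into every gene set of a collection
#'
#' @inheritParams map_variants_to_gene_set
#' @param collection A `geneset_collection`.
#' @return Named list (by `set_id`) of variant-id character vectors, with a
#'   `skipped_genes` attribute giving the per-set tally of member genes
#'   missing from the annotation.
#' @export
map_variants_to_sets <- function(variants, genes, collection) {
  maps <- purrr::map(collection$genes, function(gs) {
    map_variants_to_gene_set(variants, genes, gs)
  })
  out <- purrr::map(maps, "variant_ids")
  names(out) <- collection$set_id
  attr(out, "skipped_genes") <-
    setNames(purrr::map_int(maps, "n_skipped_genes"), collection$set_id)
  out
}

#' Exclude variants near known risk loci
#'
#' Drops every variant within `window_bp` (default 1 Mb, i.e. "1 Mb upstream
#' and downstream") of any hit on the same chromosome. Idempotent.
#'
#' @param variants Variant tibble with `chrom`, `pos`.
#' @param hits Tibble (or data frame) with `chrom`, `pos` of known hits.
#' @param window_bp Exclusion half-window in base pairs.
#' @return The filtered variant tibble.
#' @export
exclude_loci <- function(variants, hits, window_bp = 1e6) {
  stopifnot(nrow(hits) >= 1, window_bp > 0)
  drop <- rep(FALSE, nrow(variants))
  for (k in seq_len(nrow(hits))) {
    drop <- drop |
      (variants$chrom == hits$chrom[k] &
         abs(variants$pos - hits$pos[k]) <= window_bp)
  }
  variants[!drop, , drop = FALSE]
}

#' Rank pleiotropic genes across a gene-set collection
#'
#' Genes are ranked by the number of sets they belong to (descending); the top
#' `top_fraction` (by count of distinct genes, rounded up) is returned. Ties
#' at the cut are broken by lexicographic gene symbol.
#'
#' @param collection A `geneset_collection`.
#' @param top_fraction Fraction of genes to return (default 0.01, the top 1%).
#' @return Tibble `gene`, `n_sets`, sorted by decreasing membership count.
#' @export
rank_pleiotropic_genes <- function(collection, top_fraction = 0.01) {
  stopifnot(nrow(collection) >= 1, top_fraction > 0, top_fraction <= 1)
  counts <- tibble(gene = unlist(collection$genes)) %>%
    count(.data$gene, name = "n_sets") %>%
    arrange(desc(.data$n_sets), .data$gene)
  n_top <- ceiling(top_fraction * nrow(counts))
  head(counts, n_top)
}
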