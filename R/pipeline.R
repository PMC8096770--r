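#' Run the full pathway-risk analysis end-to-end on synthetic data
#'
#' Orchestrates every stage in the analysis order: simulate inputs, two-phase
#' pathway polygenic-score scan, gene-set rare-variant burden (SKAT-O),
#' case-only co-expression communities with pathway enrichment, cell-type
#' specificity-decile trend scan, SMR + HEIDI gene prioritization, and a
#' combined report (replicated sets, pleiotropy-ranked genes, SMR genes
#' intersected with communities). Each stage writes a TSV into `out_dir`
#' and a machine-readable manifest records seeds, thresholds, sizes and
#' output checksums. Reruns with the same seed are byte-identical.
#'
#' Stage problem sizes are deliberately modest (the defaults of the `sim_*`
#' generators) so a full run completes in a couple of minutes.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_perm Permutations for the PES scan. The default 500 keeps the
#'   empirical-p floor `1/(n_perm+1)` below the demonstration scan's
#'   Bonferroni line (0.05/10 sets).
#' @param scan_args,burden_args,expr_args,eqtl_args Optional named lists
#'   overriding the corresponding generator arguments. The demonstration
#'   defaults use a 10-set, 40-gene study (1000 training / 600 testing
#'   samples) so a complete run takes well under a minute.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pathway_analysis <- function(out_dir, seed = 1, n_perm = 500,
                                 scan_args = list(), burden_args = list(),
                                 expr_args = list(), eqtl_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- stage 1: pathway PES scan ------------------------------------------
  study <- stage("simulate", do.call(sim_pes_study, modifyList(
    list(seed = seed, n_ref = 1200, n_train = 1000, n_test = 600,
         n_blocks = 40, n_sets = 10),
    scan_args)))
  scan <- stage("scan", scan_pathway_pes(
    study$collection, study$variant_map, study$sumstats,
    study$train_panel, study$train_pheno,
    study$test_panel, study$test_pheno,
    prevalence = 0.2, n_perm = n_perm, seed = seed
  ))
  write_stage_tsv(scan, file.path(out_dir, "pes_scan.tsv"))
  write_stage_tsv(scan_thresholds(scan),
                  file.path(out_dir, "pes_thresholds.tsv"))

  # -- stage 2: rare-variant burden ---------------------------------------
  burden_study <- stage("simulate-burden", do.call(
    sim_burden_study, modifyList(list(seed = seed + 100L), burden_args)))
  burden <- stage("burden", scan_burden(
    burden_study$collection, burden_study$rare_variants,
    burden_study$panel, burden_study$phenotype
  ))
  write_stage_tsv(burden, file.path(out_dir, "burden_scan.tsv"))

  # -- stage 3: expression communities ------------------------------------
  expr <- stage("simulate-expression", do.call(
    sim_expression, modifyList(list(seed = seed + 200L), expr_args)))
  net <- stage("network", {
    zt <- z_transform_genes(expr)
    sel <- select_discriminative_genes(zt, seed = seed)
    graph <- case_correlation_graph(zt, genes = sel)
    part <- detect_communities(graph, seed = seed)
    truth <- attr(expr, "truth")
    pathways <- truth %>%
      filter(!is.na(.data$block)) %>%
      group_by(.data$block) %>%
      summarise(genes = list(.data$gene), .groups = "drop")
    block_sets <- new_geneset_collection(tibble(
      set_id = sprintf("REACTOME_BLOCK_%d", pathways$block),
      source = "REACTOME", n_genes = lengths(pathways$genes),
      genes = pathways$genes
    ))
    enr <- community_enrichment(part, block_sets)
    list(partition = part, enrichment = enr, selected = sel)
  })
  write_stage_tsv(net$partition, file.path(out_dir, "communities.tsv"))
  write_stage_tsv(net$enrichment,
                  file.path(out_dir, "community_enrichment.tsv"))

  # -- stage 4: cell-type decile trend ------------------------------------
  ct <- stage("celltype", {
    cts <- sim_celltype_study(n_ref = 1000, n_train = 800, n_test = 600,
                              n_blocks = 40, seed = seed + 300L)
    scan_celltype_trend(cts$specificity, cts$layout$genes, cts$sumstats,
                        cts$train_panel, cts$train_pheno,
                        cts$test_panel, cts$test_pheno,
                        prevalence = 0.2, n_pcs = 5)
  })
  write_stage_tsv(ct, file.path(out_dir, "celltype_trend.tsv"))

  # -- stage 5: SMR + HEIDI -----------------------------------------------
  qtl <- stage("simulate-eqtl", do.call(
    sim_eqtl, modifyList(list(seed = seed + 400L, scenario = "mediation"),
                         eqtl_args)))
  smr <- stage("smr", smr_scan(qtl$eqtl, qtl$gwas, qtl$ld_list))
  write_stage_tsv(smr, file.path(out_dir, "smr.tsv"))

  # -- stage 6: combined report -------------------------------------------
  report <- stage("report", {
    replicated <- scan %>%
      filter(.data$phase == "testing", .data$replicated) %>%
      pull(.data$set_id)
    pleio <- rank_pleiotropic_genes(study$collection, top_fraction = 0.01)
    overlap <- smr_community_overlap(smr, net$partition)
    list(
      replicated_sets = tibble(set_id = replicated),
      pleiotropy = pleio,
      smr_in_communities = overlap
    )
  })
  write_stage_tsv(report$replicated_sets,
                  file.path(out_dir, "replicated_sets.tsv"))
  write_stage_tsv(report$pleiotropy,
                  file.path(out_dir, "pleiotropy_top_genes.tsv"))
  write_stage_tsv(report$smr_in_communities,
                  file.path(out_dir, "smr_community_overlap.tsv"))

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pathpes")),
    seed = seed, n_perm = n_perm,
    thresholds = attr(scan, "thresholds"),
    modularity = attr(net$partition, "modularity"),
    outputs = lapply(setNames(nm = basename(outputs)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  writeLines(format_manifest(manifest), file.path(out_dir, "manifest.txt"))
  invisible(list(scan = scan, burden = burden, network = net,
                 celltype = ct, smr = smr, report = report,
                 manifest = manifest))
}

# Flat key: value rendering, stable ordering, so manifests diff cleanly.
format_manifest <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    val <- x[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(val)) {
      out <- c(out, format_manifest(val, paste0(key, ".")))
    } else {
      out <- c(out, sprintf("%s: %s", key,
                            paste(format(val, digits = 15), collapse = ", ")))
    }
  }
  out
}
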