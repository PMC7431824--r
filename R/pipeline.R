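#' Run the full differential-methylome pipeline from a config
#'
#' Orchestrates: read per-sample coverage files, merge with the minimum
#' read-count filter, per-CpG testing (t-test or pooled Fisher), windowed
#' directional DMR calling, annotation (island context, genes, cytobands,
#' nucleosome regions), direction-by-context enrichment, gene-list
#' enrichments, cytoband enrichment, per-chromosome density localization,
#' hierarchical clustering, and writes every table plus a manifest to the
#' output directory. Reruns with the same config are deterministic.
#'
#' @param config Either a path to a YAML file or a list with entries:
#'   `samples` (list of `sample_id`, `path`, `group`, optional `age`),
#'   `islands`, `genes`, `cytobands`, optional `nucleosomes`, optional
#'   named list `gene_lists`, `test_design` (`"ttest"` or `"fisher"`),
#'   `alpha`, `min_coverage`, `dmr` (fields of [dmr_config()]),
#'   `universe` (`"annotation"` or `"covered"`), `localize`
#'   (`n_boot`, `grid_size`, `bandwidth_adjust`), `seed`, `out_dir`.
#' @return Invisibly, a list with every intermediate result and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- cfg$alpha %||% 0.05
  min_coverage <- cfg$min_coverage %||% 5
  seed <- as.integer(cfg$seed %||% 1L)

  samples <- cfg$samples
  ids <- vapply(samples, function(s) s$sample_id, "")
  paths <- vapply(samples, function(s) s$path, "")
  groups <- setNames(vapply(samples, function(s) s$group, ""), ids)
  ages <- setNames(vapply(samples, function(s) {
    as.numeric(s$age %||% NA_real_)
  }, numeric(1)), ids)
  for (p in c(paths, cfg$islands, cfg$genes, cfg$cytobands)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }

  counts <- setNames(lapply(seq_along(ids), function(i) {
    read_coverage_file(paths[i], ids[i])
  }), ids)
  dataset <- merge_samples(counts, groups, min_coverage = min_coverage,
                           age = if (all(is.na(ages))) NULL else ages)

  design <- cfg$test_design %||% "ttest"
  site_results <- switch(design,
                         ttest = test_sites_ttest(dataset, alpha = alpha),
                         fisher = test_sites_fisher(dataset, alpha = alpha),
                         stop("unknown test_design: ", design))

  dcfg <- do.call(dmr_config, c(cfg$dmr, list(alpha = alpha)))
  dmrs <- call_dmrs(site_results, dcfg)

  islands <- read_bed(cfg$islands)
  genes <- read_gene_models(cfg$genes)
  cytobands <- read_cytobands(cfg$cytobands)
  nucleosomes <- if (!is.null(cfg$nucleosomes)) read_bed(cfg$nucleosomes)
  annotated <- annotate_dmrs(dmrs, islands, genes, cytobands, nucleosomes)

  universe <- gene_universe(genes, cfg$universe %||% "annotation",
                            sites = dataset$sites)
  qgenes <- dmr_genes(annotated, "any")

  ctx_enrich <- island_context_enrichment(annotated)
  band_enrich <- cytoband_enrichment(qgenes, genes, cytobands, universe,
                                     alpha = alpha)
  set_enrich <- NULL
  if (!is.null(cfg$gene_lists)) {
    set_enrich <- do.call(rbind, lapply(names(cfg$gene_lists), function(nm) {
      geneset_enrichment(qgenes, read_gene_list(cfg$gene_lists[[nm]]),
                         universe, label = nm)
    }))
    set_enrich$q_value <- benjamini_hochberg(set_enrich$p_value)
  }

  loc <- cfg$localize %||% list()
  profiles <- list(); flagged <- list()
  tss_q <- genes$tss[genes$symbol %in% qgenes]
  for (ch in unique(dmrs$chrom)) {
    all_tss <- genes$tss[genes$chrom == ch]
    dmr_tss <- genes$tss[genes$chrom == ch & genes$symbol %in% qgenes]
    if (length(dmr_tss) < 2 || length(all_tss) < 2) next
    L <- max(cytobands$end[cytobands$chrom == ch])
    profiles[[ch]] <- density_profile(
      all_tss, dmr_tss, L, chrom = ch,
      n_boot = loc$n_boot %||% 1000,
      seed = derive_seed(seed, match(ch, unique(dmrs$chrom))),
      bandwidth_adjust = loc$bandwidth_adjust %||% 0.2,
      grid_size = loc$grid_size %||% 512)
    flagged[[ch]] <- flag_divergent_bands(profiles[[ch]], cytobands)
  }

  cluster <- tryCatch(cluster_dmr_cpgs(dataset, dmrs), error = function(e) NULL)

  regression <- NULL
  if (!all(is.na(dataset$samples$age)) && nrow(dmrs)) {
    apa <- dataset$samples$group == "APA"
    pct <- methylation_percent_matrix(dataset)
    keys <- paste(dataset$sites$chrom, dataset$sites$pos)
    regression <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
      rows <- keys %in% paste(dmrs$chrom[i], dmrs$members[[i]])
      mean_pct <- colMeans(pct[rows, , drop = FALSE])
      fit <- regress_meth_on_age(mean_pct[apa], dataset$samples$age[apa])
      data.frame(chrom = dmrs$chrom[i], start = dmrs$start[i],
                 end = dmrs$end[i], direction = dmrs$direction[i],
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, p_value = fit$p_value)
    }))
  }

  # ---- outputs -------------------------------------------------------
  paths_out <- list(
    site_results = file.path(out_dir, "site_results.tsv"),
    dmrs = file.path(out_dir, "dmrs.bed"),
    annotated = file.path(out_dir, "annotated_dmrs.tsv"),
    summary = file.path(out_dir, "dmr_summary.tsv"),
    context_enrichment = file.path(out_dir, "island_context_enrichment.tsv"),
    cytoband_enrichment = file.path(out_dir, "cytoband_enrichment.tsv"))
  write_site_results(site_results, paths_out$site_results)
  write_dmrs(dmrs, paths_out$dmrs)
  write_annotated_dmrs(annotated, paths_out$annotated)
  write.table(summarize_dmrs(dmrs), paths_out$summary, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_enrichment(ctx_enrich, paths_out$context_enrichment)
  write_enrichment(band_enrich, paths_out$cytoband_enrichment)
  if (!is.null(set_enrich)) {
    paths_out$geneset_enrichment <- file.path(out_dir,
                                              "geneset_enrichment.tsv")
    write_enrichment(set_enrich, paths_out$geneset_enrichment)
  }
  for (ch in names(profiles)) {
    p <- file.path(out_dir, paste0("density_", ch, ".tsv"))
    write_density_profile(profiles[[ch]], p)
    paths_out[[paste0("density_", ch)]] <- p
  }
  if (!is.null(cluster)) {
    paths_out$cluster_labels <- file.path(out_dir, "cluster_labels.tsv")
    write.table(data.frame(sample_id = names(cluster$labels),
                           cluster = cluster$labels),
                paths_out$cluster_labels, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(regression)) {
    paths_out$regression <- file.path(out_dir, "dmr_age_regression.tsv")
    write.table(regression, paths_out$regression, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methage")),
    seed = seed, alpha = alpha, min_coverage = min_coverage,
    test_design = design,
    dmr = unclass(dcfg)[c("lambda_bp", "min_cpgs", "min_mean_abs_delta",
                          "mean_over")],
    inputs = as.list(tools::md5sum(c(paths, cfg$islands, cfg$genes,
                                     cfg$cytobands))),
    stages = names(paths_out))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(dataset = dataset, site_results = site_results,
                 dmrs = dmrs, annotated = annotated,
                 context_enrichment = ctx_enrich,
                 cytoband_enrichment = band_enrich,
                 geneset_enrichment = set_enrich,
                 profiles = profiles, flagged_bands = flagged,
                 cluster = cluster, regression = regression,
                 manifest = manifest, paths = paths_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a study, run the pipeline stages, and score recovery
#'
#' The package's self-contained benchmark: generates a synthetic cohort
#' with spiked DMRs, applies the coverage filter, per-CpG t-tests and the
#' DMR caller, then scores (i) region-level sensitivity — the fraction of
#' spiked regions overlapped by a called DMR of the matching direction,
#' (ii) the region-level false-discovery proportion — called DMRs
#' overlapping no spiked region, (iii) recovery of the group labels by the
#' two-branch hierarchical clustering cut (adjusted Rand index), and
#' (iv) detection of the planted gene-set enrichments.
#'
#' @param config A [sim_config()].
#' @param dmr_cfg A [dmr_config()].
#' @param out Optional path for a one-row report TSV.
#' @return List: `sensitivity`, `fdp`, `ari`, `n_dmrs`, `enrichment`
#'   (per planted gene set: OR, p, q, detected), plus the underlying
#'   objects.
#' @export
run_simulation_study <- function(config = sim_config(),
                                 dmr_cfg = dmr_config(), out = NULL) {
  genome <- simulate_genome(config)
  sim <- simulate_counts(genome, config)
  dataset <- filter_coverage(sim$dataset)
  site_results <- test_sites_ttest(dataset, alpha = dmr_cfg$alpha)
  dmrs <- call_dmrs(site_results, dmr_cfg)

  truth <- sim$truth$spiked_dmrs
  if (nrow(truth) && nrow(dmrs)) {
    tg <- as_granges(truth); dg <- as_granges(dmrs)
    hits <- GenomicRanges::findOverlaps(tg, dg)
    dir_match <- truth$direction[S4Vectors::queryHits(hits)] ==
      dmrs$direction[S4Vectors::subjectHits(hits)]
    recovered <- unique(S4Vectors::queryHits(hits)[dir_match])
    sensitivity <- length(recovered) / nrow(truth)
    false_call <- !(seq_len(nrow(dmrs)) %in% S4Vectors::subjectHits(hits))
    fdp <- sum(false_call) / nrow(dmrs)
  } else {
    sensitivity <- if (nrow(truth)) 0 else NA_real_
    fdp <- if (nrow(dmrs)) 1 else 0
  }

  ari <- NA_real_
  cl <- tryCatch(cluster_dmr_cpgs(dataset, dmrs), error = function(e) NULL)
  if (!is.null(cl)) {
    ari <- mclust::adjustedRandIndex(cl$labels, dataset$samples$group)
  }

  annotated <- annotate_dmrs(dmrs, genome$islands, genome$genes,
                             genome$cytobands, genome$nucleosomes)
  qgenes <- dmr_genes(annotated, "any")
  universe <- gene_universe(genome$genes)
  enrichment <- NULL
  if (length(sim$truth$gene_sets)) {
    enrichment <- do.call(rbind, lapply(names(sim$truth$gene_sets),
                                        function(nm) {
      geneset_enrichment(qgenes, sim$truth$gene_sets[[nm]], universe,
                         label = nm)
    }))
    enrichment$q_value <- benjamini_hochberg(enrichment$p_value)
    enrichment$detected <- enrichment$q_value <= 0.05 &
      enrichment$odds_ratio > 1
  }

  report <- data.frame(seed = config$seed, n_sites = nrow(dataset$sites),
                       n_spiked = nrow(truth), n_dmrs = nrow(dmrs),
                       sensitivity = sensitivity, fdp = fdp, ari = ari)
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sensitivity = sensitivity, fdp = fdp, ari = ari,
       n_dmrs = nrow(dmrs), report = report, enrichment = enrichment,
       dataset = dataset, site_results = site_results, dmrs = dmrs,
       annotated = annotated, truth = sim$truth, genome = genome)
}
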