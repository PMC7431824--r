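#' Fisher exact test with odds ratio and Woolf confidence interval
#'
#' The 2x2 workhorse behind every enrichment statistic in the package.
#' The p-value is the two-sided Fisher exact probability (minimum
#' likelihood rule). The odds ratio is the sample cross-product
#' `(a*d)/(b*c)` and its 95% CI is the Woolf log-odds interval
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`; when any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to all four cells for the
#' OR and CI (never for the p-value).
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` is the
#'   in-query-and-target cell.
#' @param label Optional row label.
#' @return One-row data.frame of class `EnrichmentResult`: `label`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fisher_or_ci <- function(a, b, c, d, label = NA_character_) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("all-zero 2x2 table")
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
  cc <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  aa <- a + cc; bb <- b + cc; ccell <- c + cc; dd <- d + cc
  or <- (aa * dd) / (bb * ccell)
  se <- sqrt(1 / aa + 1 / bb + 1 / ccell + 1 / dd)
  res <- data.frame(label = label, a = a, b = b, c = c, d = d,
                    odds_ratio = or,
                    ci_low = exp(log(or) - 1.96 * se),
                    ci_high = exp(log(or) + 1.96 * se),
                    p_value = min(1, p))
  class(res) <- c("EnrichmentResult", class(res))
  res
}

#' Gene-set overlap enrichment
#'
#' Tests whether `query_genes` (e.g. DMR-associated genes) overlap
#' `target_set` (e.g. a disease gene list) more than expected given the
#' gene universe. Both sets are intersected with the universe before
#' counting; `a` = shared, `b` = query only, `c` = target only,
#' `d` = neither.
#'
#' @param query_genes,target_set Character vectors of gene symbols.
#' @param universe Character vector of all considered symbols.
#' @param label Optional label.
#' @return An `EnrichmentResult` row.
#' @export
geneset_enrichment <- function(query_genes, target_set, universe,
                               label = NA_character_) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe")
  q <- intersect(unique(toupper(query_genes)), universe)
  t <- intersect(unique(toupper(target_set)), universe)
  a <- length(intersect(q, t))
  b <- length(setdiff(q, t))
  c <- length(setdiff(t, q))
  d <- length(universe) - a - b - c
  fisher_or_ci(a, b, c, d, label = label)
}

#' Directional sperm-blastocyst DMR-gene overlap enrichment
#'
#' For each methylation direction, the query is the set of genes with at
#' least one DMR of that direction in the first (sperm-style) dataset and
#' the target is the same in the second (blastocyst-style) dataset; `"any"`
#' ignores direction. Gene sets are intentionally not deduplicated across
#' directions: a gene carrying both a hyper- and a hypomethylated DMR
#' contributes to both directional overlaps.
#'
#' @param sperm_annotated,blast_annotated `AnnotatedDMR` data.frames
#'   annotated against the same gene models.
#' @param universe Gene universe (see [gene_universe()]).
#' @return List with `results` (EnrichmentResult rows for hyper, hypo, any)
#'   and `overlap_genes` (named list of the shared gene symbols).
#' @export
directional_overlap <- function(sperm_annotated, blast_annotated, universe) {
  dirs <- c("hyper", "hypo", "any")
  res <- list(); genes <- list()
  for (d in dirs) {
    q <- dmr_genes(sperm_annotated, d)
    t <- dmr_genes(blast_annotated, d)
    res[[d]] <- geneset_enrichment(q, t, universe, label = d)
    genes[[d]] <- intersect(q, t)
  }
  list(results = do.call(rbind, res), overlap_genes = genes)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone in the sorted order,
#' capped at 1, returned in input order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Default gene universe
#'
#' Either every symbol in the gene models (`source = "annotation"`, the
#' default) or only genes containing at least one tested CpG
#' (`source = "covered"`).
#'
#' @param genes Gene models.
#' @param source `"annotation"` or `"covered"`.
#' @param sites Optional data.frame `chrom`, `pos` of tested CpGs
#'   (required for `"covered"`).
#' @return Character vector of symbols.
#' @export
gene_universe <- function(genes, source = c("annotation", "covered"),
                          sites = NULL) {
  source <- match.arg(source)
  if (source == "annotation") return(sort(unique(genes$symbol)))
  if (is.null(sites)) stop("covered universe requires the tested CpG sites")
  hits <- GenomicRanges::findOverlaps(pos_granges(sites$chrom, sites$pos),
                                      as_granges(genes))
  sort(unique(genes$symbol[S4Vectors::subjectHits(hits)]))
}

#' Cytoband enrichment of DMR-associated genes
#'
#' Maps every universe gene to the single cytoband containing its promoter
#' start site, then tests each band for over-representation of
#' DMR-associated genes (Fisher exact, BH-adjusted across bands). A band
#' is called significant at `p <= .05` and `q <= .05`.
#'
#' @param query_genes DMR-associated gene symbols.
#' @param genes Gene models (must cover the universe).
#' @param cytobands Cytoband table from [read_cytobands()].
#' @param universe Gene universe; defaults to all gene-model symbols.
#' @param alpha Significance level for both p and q (default .05).
#' @return data.frame: one `EnrichmentResult` row per band plus `q_value`
#'   and `significant`.
#' @export
cytoband_enrichment <- function(query_genes, genes, cytobands,
                                universe = NULL, alpha = 0.05) {
  if (is.null(universe)) universe <- gene_universe(genes)
  universe <- unique(toupper(universe))
  g <- genes[match(universe, genes$symbol), , drop = FALSE]
  if (anyNA(g$symbol)) stop("universe contains genes absent from the models")
  hits <- GenomicRanges::findOverlaps(pos_granges(g$chrom, g$tss),
                                      as_granges(cytobands))
  band_of <- rep(NA_integer_, nrow(g))
  band_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  if (anyNA(band_of)) {
    stop("gene '", g$symbol[which(is.na(band_of))[1]],
         "' has a promoter start site outside all cytobands")
  }
  query <- intersect(unique(toupper(query_genes)), universe)
  in_query <- universe %in% query
  res <- do.call(rbind, lapply(seq_len(nrow(cytobands)), function(bi) {
    on_band <- band_of == bi
    fisher_or_ci(sum(in_query & on_band), sum(in_query & !on_band),
                 sum(!in_query & on_band), sum(!in_query & !on_band),
                 label = cytobands$name[bi])
  }))
  res$q_value <- benjamini_hochberg(res$p_value)
  res$significant <- res$p_value <= alpha & res$q_value <= alpha
  res
}

#' Write enrichment results as TSV
#' @param results `EnrichmentResult` data.frame.
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
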