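#' Strand-aware promoter windows for gene models
#'
#' The promoter covers `upstream` bp before and `downstream` bp after the
#' transcription start site, in the direction of transcription. On the
#' plus strand this is `[tss - upstream, tss + downstream)`; on the minus
#' strand the window is mirrored around the TSS. Coordinates are clipped
#' at zero.
#'
#' @param genes data.frame from [read_gene_models()].
#' @param upstream,downstream Window extents in bp (defaults 2000 / 500).
#' @return data.frame `symbol`, `chrom`, `start`, `end`.
#' @export
gene_promoters <- function(genes, upstream = 2000, downstream = 500) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  data.frame(symbol = genes$symbol, chrom = genes$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end))
}

#' Build the CpG island / shore / shelf context map
#'
#' Shores are the 2 kb flanks on either side of a (merged) island, minus
#' the islands themselves; shelves are the next 2 kb beyond the shores,
#' minus islands and shores. The three context sets are pairwise disjoint
#' by construction; everything else is open sea.
#'
#' @param islands data.frame of island intervals (`chrom`, `start`, `end`).
#' @param flank Width of each context ring in bp (default 2000).
#' @return List of class `island_context` with `GRanges` elements `island`,
#'   `shore`, `shelf`.
#' @export
build_island_context <- function(islands, flank = 2000) {
  isl <- GenomicRanges::reduce(as_granges(islands))
  expand <- function(gr, by) {
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr),
      ranges = IRanges::IRanges(
        start = pmax(1L, GenomicRanges::start(gr) - as.integer(by)),
        end = GenomicRanges::end(gr) + as.integer(by)))
  }
  shore <- GenomicRanges::setdiff(expand(isl, flank), isl)
  shelf <- GenomicRanges::setdiff(expand(isl, 2 * flank),
                                  GenomicRanges::union(isl, expand(isl, flank)))
  structure(list(island = isl, shore = shore, shelf = shelf),
            class = "island_context")
}

#' Classify positions into island / shore / shelf / open sea
#'
#' @param context An `island_context` from [build_island_context()].
#' @param chrom,pos Vectors of 0-based positions.
#' @return Character vector with precedence island > shore > shelf >
#'   open_sea.
#' @export
classify_positions <- function(context, chrom, pos) {
  gr <- pos_granges(chrom, pos)
  out <- rep("open_sea", length(gr))
  for (ctx in c("shelf", "shore", "island")) {
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, context[[ctx]]))
    out[hit] <- ctx
  }
  out
}

#' Annotate DMRs with genomic context
#'
#' Attaches to each DMR: its island context (the highest-precedence context
#' any member CpG falls in), the genes whose body or strand-aware promoter
#' it overlaps, every cytoband its span intersects, and whether it overlaps
#' a nucleosome-retention region by at least one bp.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param islands Island intervals (data.frame) or an `island_context`.
#' @param genes Gene models from [read_gene_models()].
#' @param cytobands Cytoband table from [read_cytobands()]; the bands must
#'   cover every chromosome carrying a DMR.
#' @param nucleosomes Optional nucleosome-retention intervals.
#' @param promoter_upstream,promoter_downstream Promoter rule passed to
#'   [gene_promoters()].
#' @return `AnnotatedDMR` data.frame: the DMR columns plus `island_context`,
#'   list-columns `genes` and `cytobands`, and `nucleosome_overlap`.
#' @export
annotate_dmrs <- function(dmrs, islands, genes, cytobands,
                          nucleosomes = NULL,
                          promoter_upstream = 2000,
                          promoter_downstream = 500) {
  context <- if (inherits(islands, "island_context")) islands else
    build_island_context(islands)
  missing_ch <- setdiff(unique(dmrs$chrom), unique(cytobands$chrom))
  if (length(missing_ch)) {
    stop("cytobands missing for chromosome ", missing_ch[1])
  }
  n <- nrow(dmrs)
  dmr_gr <- as_granges(dmrs)

  # island context from member CpGs, precedence island > shore > shelf
  ctx_rank <- c(open_sea = 0, shelf = 1, shore = 2, island = 3)
  mem_lens <- lengths(dmrs$members)
  mem_cls <- classify_positions(context,
                                rep(dmrs$chrom, mem_lens),
                                unlist(dmrs$members))
  island_context <- vapply(split(ctx_rank[mem_cls], rep(seq_len(n), mem_lens)),
                           function(r) names(which.max(r)),
                           character(1), USE.NAMES = FALSE)

  # gene association: body or promoter overlap
  prom <- gene_promoters(genes, promoter_upstream, promoter_downstream)
  body_hits <- GenomicRanges::findOverlaps(dmr_gr, as_granges(genes))
  prom_hits <- GenomicRanges::findOverlaps(dmr_gr, as_granges(prom))
  gene_sets <- lapply(seq_len(n), function(i) {
    sort(unique(c(
      genes$symbol[S4Vectors::subjectHits(body_hits)[
        S4Vectors::queryHits(body_hits) == i]],
      prom$symbol[S4Vectors::subjectHits(prom_hits)[
        S4Vectors::queryHits(prom_hits) == i]])))
  })

  band_hits <- GenomicRanges::findOverlaps(dmr_gr, as_granges(cytobands))
  band_sets <- lapply(seq_len(n), function(i) {
    sort(unique(cytobands$name[S4Vectors::subjectHits(band_hits)[
      S4Vectors::queryHits(band_hits) == i]]))
  })

  nuc_overlap <- rep(FALSE, n)
  if (!is.null(nucleosomes) && nrow(nucleosomes)) {
    hits <- GenomicRanges::findOverlaps(dmr_gr, as_granges(nucleosomes))
    nuc_overlap[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  out <- dmrs
  out$island_context <- if (n) island_context else character(0)
  out$genes <- gene_sets
  out$cytobands <- band_sets
  out$nucleosome_overlap <- nuc_overlap
  class(out) <- unique(c("AnnotatedDMR", class(out)))
  out
}

#' Genes associated with DMRs of a given direction
#'
#' @param annotated `AnnotatedDMR` data.frame.
#' @param direction `"hyper"`, `"hypo"`, or `"any"`.
#' @return Sorted unique gene symbols.
#' @export
dmr_genes <- function(annotated, direction = "any") {
  keep <- if (direction == "any") rep(TRUE, nrow(annotated)) else
    annotated$direction == direction
  sort(unique(unlist(annotated$genes[keep])))
}

#' Direction-by-context enrichment of DMRs
#'
#' For each island context, tests whether hypomethylated DMRs fall in that
#' context more often than hypermethylated DMRs do, with a two-sided Fisher
#' exact test on the 2x2 table (direction x in-context). The odds ratio is
#' oriented so that values above 1 mean the context is enriched among
#' hypomethylated DMRs.
#'
#' @param annotated `AnnotatedDMR` data.frame containing both directions.
#' @return data.frame of [fisher_or_ci()] results, one row per context,
#'   with a `testable` flag (FALSE when a direction is absent).
#' @export
island_context_enrichment <- function(annotated) {
  contexts <- c("island", "shore", "shelf", "open_sea")
  hypo <- annotated$island_context[annotated$direction == "hypo"]
  hyper <- annotated$island_context[annotated$direction == "hyper"]
  testable <- length(hypo) > 0 && length(hyper) > 0
  do.call(rbind, lapply(contexts, function(ctx) {
    if (!testable) {
      return(data.frame(label = ctx, a = NA, b = NA, c = NA, d = NA,
                        odds_ratio = NA, ci_low = NA, ci_high = NA,
                        p_value = NA, testable = FALSE))
    }
    res <- fisher_or_ci(sum(hypo == ctx), sum(hypo != ctx),
                        sum(hyper == ctx), sum(hyper != ctx), label = ctx)
    res$testable <- TRUE
    res
  }))
}

#' Write annotated DMRs as TSV (genes and bands comma-joined)
#' @param annotated `AnnotatedDMR` data.frame.
#' @param path Output path.
#' @export
write_annotated_dmrs <- function(annotated, path) {
  df <- data.frame(
    chrom = annotated$chrom, start = annotated$start, end = annotated$end,
    direction = annotated$direction, n_sig_cpgs = annotated$n_sig_cpgs,
    mean_delta = annotated$mean_delta, width = annotated$width,
    island_context = annotated$island_context,
    genes = vapply(annotated$genes, paste, "", collapse = ","),
    cytobands = vapply(annotated$cytobands, paste, "", collapse = ","),
    nucleosome_overlap = annotated$nucleosome_overlap)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
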