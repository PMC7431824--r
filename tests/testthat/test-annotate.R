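test_that("island context map follows the 2kb shore / 2kb shelf definition", {
  ctx <- build_island_context(data.frame(chrom = "chr1", start = 10000L,
                                         end = 11000L))
  cls <- classify_positions(ctx, rep("chr1", 8),
                            c(10500, 9500, 12999, 7000, 13001, 6000, 5000,
                              15000))
  expect_equal(cls, c("island", "shore", "shore", "shelf", "shelf", "shelf",
                      "open_sea", "open_sea"))
  # contexts are pairwise disjoint
  expect_equal(length(GenomicRanges::intersect(ctx$island, ctx$shore)), 0)
  expect_equal(length(GenomicRanges::intersect(ctx$shore, ctx$shelf)), 0)
  expect_equal(length(GenomicRanges::intersect(ctx$island, ctx$shelf)), 0)
})

test_that("two islands 1kb apart leave an all-shore gap (precedence)", {
  ctx <- build_island_context(data.frame(chrom = "chr1",
                                         start = c(10000L, 12000L),
                                         end = c(11000L, 13000L)))
  gap <- 11000:11999
  cls <- classify_positions(ctx, rep("chr1", length(gap)), gap)
  expect_true(all(cls == "shore"))
  # oracle by direct set algebra on positions
  flat <- function(gr) {
    unlist(lapply(seq_along(gr), function(i) {
      seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    }))
  }
  isl_bp <- flat(ctx$island); shore_bp <- flat(ctx$shore)
  shelf_bp <- flat(ctx$shelf)
  expect_equal(length(intersect(isl_bp, shore_bp)), 0)
  expect_equal(length(intersect(shore_bp, shelf_bp)), 0)
  manual_shore <- setdiff(unlist(lapply(c(10000, 12000), function(s) {
    c(seq(s - 2000 + 1, s), seq(s + 1000 + 1, s + 3000))
  })), isl_bp)
  expect_setequal(shore_bp, manual_shore)
})

mk_dmr <- function(chrom, start, end, members, direction = "hypo") {
  d <- data.frame(chrom = chrom, start = as.integer(start),
                  end = as.integer(end), direction = direction,
                  n_sig_cpgs = length(members), mean_delta = -20,
                  width = end - start)
  d$members <- list(as.integer(members))
  class(d) <- c("DMR", class(d))
  d
}

fixture_annotation <- function() {
  list(
    islands = data.frame(chrom = "chr1", start = 10000L, end = 11000L),
    genes = data.frame(symbol = c("GPLUS", "GMINUS", "GFAR"),
                       chrom = "chr1", strand = c("+", "-", "+"),
                       start = c(20000L, 5000L, 80000L),
                       end = c(30000L, 9000L, 90000L),
                       tss = c(20000L, 8999L, 80000L)),
    cytobands = data.frame(chrom = "chr1", start = c(0L, 50000L),
                           end = c(50000L, 100000L),
                           name = c("1p1.1", "1q1.1"),
                           band = c("p1.1", "q1.1"), stain = "gneg"),
    nucleosomes = data.frame(chrom = "chr1", start = 10450L, end = 10600L))
}

test_that("gene association covers bodies and strand-aware promoters", {
  ann <- fixture_annotation()
  # promoter of GPLUS (+, tss 20000) = [18000, 20500)
  d1 <- mk_dmr("chr1", 18100, 18200, c(18100, 18150, 18199))
  # promoter of GMINUS (-, tss 8999) mirrored = [8500, 11000)
  d2 <- mk_dmr("chr1", 10500, 10900, c(10500, 10700, 10899))
  # no gene anywhere near
  d3 <- mk_dmr("chr1", 60000, 60500, c(60000, 60200, 60499))
  dmrs <- rbind(d1, d2, d3)
  class(dmrs) <- c("DMR", "data.frame")
  out <- annotate_dmrs(dmrs, ann$islands, ann$genes, ann$cytobands,
                       ann$nucleosomes)
  expect_equal(out$genes[[1]], "GPLUS")
  expect_equal(out$genes[[2]], "GMINUS")
  expect_equal(out$genes[[3]], character(0))
  expect_equal(out$island_context, c("open_sea", "island", "open_sea"))
  expect_true(out$nucleosome_overlap[2])
  expect_false(out$nucleosome_overlap[1])
})

test_that("cytoband overlap reports all straddled bands and missing chroms error", {
  ann <- fixture_annotation()
  d <- mk_dmr("chr1", 49000, 51000, c(49000, 49950, 50950))
  out <- annotate_dmrs(d, ann$islands, ann$genes, ann$cytobands)
  expect_setequal(out$cytobands[[1]], c("1p1.1", "1q1.1"))
  d2 <- mk_dmr("chr9", 100, 400, c(100, 200, 399))
  expect_error(annotate_dmrs(d2, ann$islands, ann$genes, ann$cytobands),
               "cytobands missing")
})

test_that("gene association matches a brute-force all-pairs oracle", {
  set.seed(5)
  genes <- data.frame(symbol = sprintf("G%03d", 1:60), chrom = "chr1",
                      strand = sample(c("+", "-"), 60, replace = TRUE),
                      start = as.integer(sample.int(2e5, 60)))
  genes$end <- genes$start + 2000L
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  bands <- data.frame(chrom = "chr1", start = 0L, end = 300000L,
                      name = "1p1.1", band = "p1.1", stain = "gneg")
  dmrs <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample.int(2e5, 1)
    mk_dmr("chr1", s, s + 300, c(s, s + 150, s + 299))
  }))
  class(dmrs) <- c("DMR", "data.frame")
  out <- annotate_dmrs(dmrs, fixture_annotation()$islands, genes, bands)
  prom <- gene_promoters(genes)
  for (i in seq_len(nrow(dmrs))) {
    want <- sort(unique(c(
      genes$symbol[pmax(genes$start, dmrs$start[i]) <
                     pmin(genes$end, dmrs$end[i])],
      prom$symbol[pmax(prom$start, dmrs$start[i]) <
                    pmin(prom$end, dmrs$end[i])])))
    expect_equal(out$genes[[i]], want)
  }
})

test_that("direction-by-context enrichment follows the cross-product OR", {
  mk_batch <- function(n, direction, ctx) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      d <- mk_dmr("chr1", 1000 * i, 1000 * i + 10,
                  c(1000 * i, 1000 * i + 5, 1000 * i + 9), direction)
      d$island_context <- ctx
      d
    }))
  }
  ann <- rbind(mk_batch(30, "hypo", "island"), mk_batch(10, "hypo", "open_sea"),
               mk_batch(10, "hyper", "island"), mk_batch(30, "hyper", "open_sea"))
  class(ann) <- c("AnnotatedDMR", "DMR", "data.frame")
  res <- island_context_enrichment(ann)
  isl <- res[res$label == "island", ]
  expect_equal(isl$odds_ratio, 9)
  expect_true(isl$p_value < 0.05)

  sym <- rbind(mk_batch(10, "hypo", "island"), mk_batch(10, "hyper", "island"),
               mk_batch(5, "hypo", "shore"), mk_batch(5, "hyper", "shore"))
  class(sym) <- c("AnnotatedDMR", "DMR", "data.frame")
  res2 <- island_context_enrichment(sym)
  expect_equal(res2[res2$label == "island", "odds_ratio"], 1)
  expect_equal(res2[res2$label == "island", "p_value"], 1)
  # all DMRs in one context: degenerate margins give p = 1
  expect_equal(res2[res2$label == "shelf", "p_value"], 1)

  onedir <- mk_batch(5, "hypo", "island")
  class(onedir) <- c("AnnotatedDMR", "DMR", "data.frame")
  expect_false(any(island_context_enrichment(onedir)$testable))
})
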