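test_that("fisher_or_ci reproduces the closed-form OR and Woolf CI", {
  r <- fisher_or_ci(20, 80, 10, 190)
  expect_equal(r$odds_ratio, 4.75)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 190)
  expect_equal(r$ci_low, exp(log(4.75) - 1.96 * se), tolerance = 1e-10)
  expect_equal(r$ci_high, exp(log(4.75) + 1.96 * se), tolerance = 1e-10)
  expect_equal(round(r$ci_low, 2), 2.13)
  expect_equal(round(r$ci_high, 2), 10.6)

  sym <- fisher_or_ci(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  z <- fisher_or_ci(10, 0, 0, 10)
  expect_equal(z$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  # Haldane-Anscombe corrected OR and a finite CI
  expect_equal(z$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_true(is.finite(z$ci_low) && is.finite(z$ci_high))
  expect_true(z$ci_low <= z$odds_ratio && z$odds_ratio <= z$ci_high)

  expect_error(fisher_or_ci(0, 0, 0, 0), "all-zero")
})

test_that("fisher p matches exhaustive enumeration on random tables", {
  set.seed(9)
  for (i in 1:100) {
    tab <- as.integer(rmultinom(1, sample(4:40, 1), runif(4)))
    expect_equal(fisher_or_ci(tab[1], tab[2], tab[3], tab[4])$p_value,
                 fisher_p_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("gene-set enrichment counts the 2x2 cells from the universe", {
  universe <- sprintf("G%04d", 1:100)
  # disjoint split: anti-enrichment
  r <- geneset_enrichment(universe[1:50], universe[51:100], universe)
  expect_equal(r$a, 0)
  expect_lt(r$odds_ratio, 1)
  # query inside target: maximal overlap
  r2 <- geneset_enrichment(universe[1:10], universe[1:30], universe)
  expect_equal(r2$a, 10)
  expect_gt(r2$odds_ratio, 1)
  # symbols outside the universe are ignored
  r3 <- geneset_enrichment(c(universe[1:10], "NOT_A_GENE"), universe[1:30],
                           universe)
  expect_equal(r3$a + r3$b, 10)
  expect_error(geneset_enrichment("A", "B", character(0)), "empty")
})

test_that("planted gene-set overlap is detected with OR > 1", {
  set.seed(31)
  universe <- sprintf("G%05d", 1:5000)
  hits <- 0
  for (i in 1:100) {
    query <- sample(universe, 200)
    n_in <- 100  # f = 0.5 of the target drawn from the query
    target <- c(sample(query, n_in),
                sample(setdiff(universe, query), 100))
    r <- geneset_enrichment(query, target, universe)
    if (r$odds_ratio > 1 && r$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("directional overlap builds the expected tables per direction", {
  mk_ann <- function(genes_by_dir) {
    rows <- lapply(names(genes_by_dir), function(dir) {
      lapply(genes_by_dir[[dir]], function(g) {
        d <- data.frame(chrom = "chr1", start = 1L, end = 10L,
                        direction = dir, n_sig_cpgs = 3L, mean_delta = 20,
                        width = 9L)
        d$members <- list(c(1L, 5L, 9L))
        d$island_context <- "open_sea"
        d$genes <- list(g)
        d$cytobands <- list("1p1.1")
        d$nucleosome_overlap <- FALSE
        d
      })
    })
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    class(out) <- c("AnnotatedDMR", "DMR", "data.frame")
    out
  }
  universe <- c(LETTERS[1:6], sprintf("U%02d", 1:94))
  sperm <- mk_ann(list(hyper = c("A", "B", "C")))
  blast <- mk_ann(list(hyper = c("B", "C", "D")))
  ov <- directional_overlap(sperm, blast, universe)
  hyper <- ov$results[ov$results$label == "hyper", ]
  # a = |{B,C}|, b = |{A}|, c = |{D}|, d = the remaining 96 universe genes
  expect_equal(unlist(hyper[, c("a", "b", "c", "d")], use.names = FALSE),
               c(2, 1, 1, 96))
  expect_setequal(ov$overlap_genes$hyper, c("B", "C"))

  # identical sets: overlap is the full set
  same <- directional_overlap(sperm, sperm, universe)
  expect_equal(same$results[same$results$label == "hyper", "a"], 3)
  # disjoint sets: a = 0; with sets large enough that the corrected
  # cross-product is informative, the OR drops below 1
  big_s <- mk_ann(list(hyper = universe[1:40]))
  big_b <- mk_ann(list(hyper = universe[41:80]))
  dis <- directional_overlap(big_s, big_b, universe)
  expect_equal(dis$results[dis$results$label == "hyper", "a"], 0)
  expect_lt(dis$results[dis$results$label == "hyper", "odds_ratio"], 1)

  # a gene with both directions counts in both directional overlaps
  both_s <- mk_ann(list(hyper = c("A", "B"), hypo = c("A", "C")))
  both_b <- mk_ann(list(hyper = c("A"), hypo = c("A")))
  both <- directional_overlap(both_s, both_b, universe)
  expect_equal(both$overlap_genes$hyper, "A")
  expect_equal(both$overlap_genes$hypo, "A")
  expect_gte(both$results[both$results$label == "any", "a"],
             max(both$results[both$results$label == "hyper", "a"],
                 both$results[both$results$label == "hypo", "a"]))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("cytoband enrichment finds a planted band and not a null", {
  set.seed(23)
  n_bands <- 20
  bands <- data.frame(chrom = "chr1",
                      start = as.integer(seq(0, 19) * 1000),
                      end = as.integer(seq(1, 20) * 1000),
                      name = sprintf("1p%02d", 1:20),
                      band = sprintf("p%02d", 1:20), stain = "gneg")
  n_genes <- 1000
  detected <- 0; null_hits <- integer(20)
  for (rep in 1:20) {
    # 5% of the universe on band 1; gene TSS uniform within its band
    band_of <- c(rep(1, 50), sample(2:n_bands, n_genes - 50, replace = TRUE))
    genes <- data.frame(symbol = sprintf("G%04d", 1:n_genes), chrom = "chr1",
                        strand = "+",
                        start = as.integer((band_of - 1) * 1000 +
                                             sample(0:990, n_genes, TRUE)))
    genes$end <- genes$start + 5L
    genes$tss <- genes$start
    # planted: 30% of 100 DMR genes on band 1
    q_planted <- c(sample(genes$symbol[band_of == 1], 30),
                   sample(genes$symbol[band_of != 1], 70))
    res <- cytoband_enrichment(q_planted, genes, bands)
    if (res$significant[res$label == "1p01"]) detected <- detected + 1
    # proportional null: uniform subsample of the universe
    q_null <- sample(genes$symbol, 100)
    resn <- cytoband_enrichment(q_null, genes, bands)
    null_hits[rep] <- sum(resn$significant)
  }
  expect_gte(detected, 19)
  expect_lte(mean(null_hits), 1)

  # degenerate: one band holding every gene
  one <- data.frame(chrom = "chr1", start = 0L, end = 100000L,
                    name = "1p1", band = "p1", stain = "gneg")
  genes <- data.frame(symbol = c("A", "B", "C", "D"), chrom = "chr1",
                      strand = "+", start = c(10L, 20L, 30L, 40L),
                      end = c(15L, 25L, 35L, 45L), tss = c(10L, 20L, 30L, 40L))
  res1 <- cytoband_enrichment(c("A", "B"), genes, one)
  expect_equal(res1$p_value, 1)
  # gene outside all bands errors
  genes$tss[1] <- 200000L
  genes$start[1] <- 200000L; genes$end[1] <- 200005L
  expect_error(cytoband_enrichment(c("A"), genes, one), "outside all cytobands")
})
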