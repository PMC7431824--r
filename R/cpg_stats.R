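#' Methylation percentage from read counts
#'
#' Methylated reads divided by total reads reporting the cytosine, times
#' 100. Errors on zero total reads: callers are expected to have applied
#' the coverage filter first.
#'
#' @param n_meth,n_unmeth Non-negative counts (vectorized).
#' @return Percentage in \[0, 100\].
#' @export
site_methylation_percent <- function(n_meth, n_unmeth) {
  total <- n_meth + n_unmeth
  if (any(total <= 0)) stop("methylation percentage undefined at zero reads")
  100 * n_meth / total
}

#' Smallest detectable methylation difference at a given coverage
#'
#' With a minimum read-count filter of `min_coverage`, adjacent
#' representable methylation levels at the minimum depth differ by
#' `100 / min_coverage` percent — the theoretical resolution of the assay.
#'
#' @param min_coverage Minimum reads per site (default 5, giving 20).
#' @return Resolution in percentage points.
#' @export
methylation_resolution <- function(min_coverage = 5) {
  stopifnot(min_coverage >= 1)
  100 / min_coverage
}

# shared post-processing: significance flag and direction
finish_site_results <- function(res, alpha) {
  res$p_value <- pmin(pmax(res$p_value, 0), 1)
  res$significant <- res$p_value <= alpha
  res$direction <- ifelse(!res$significant | res$delta == 0, "none",
                          ifelse(res$delta > 0, "hyper", "hypo"))
  class(res) <- c("SiteTestResult", class(res))
  res
}

#' Per-CpG two-sample t-test on methylation percentages
#'
#' The sperm-style design: each sample contributes one methylation
#' percentage per site and groups are compared with a two-sided unpaired
#' t-test (Welch by default; set `var_equal = TRUE` for the pooled-variance
#' Student form). Sites where both groups have zero variance get p = 1 when
#' the means agree (no signal) and p = 0 when they differ (perfect
#' separation).
#'
#' @param dataset A `MethylationDataset`; every site must have positive
#'   coverage in all samples and each group needs >= 2 samples.
#' @param alpha Significance threshold on the per-CpG p-value (default .05).
#' @param var_equal Use the pooled-variance Student t-test instead of Welch.
#' @return data.frame (class `SiteTestResult`) with columns `chrom`, `pos`,
#'   `mean_young`, `mean_apa`, `delta` (APA - young), `p_value`,
#'   `significant`, `direction`.
#' @export
test_sites_ttest <- function(dataset, alpha = 0.05, var_equal = FALSE) {
  grp <- dataset$samples$group
  if (sum(grp == "young") < 2 || sum(grp == "APA") < 2) {
    stop("t-test requires >= 2 samples per group")
  }
  pct <- methylation_percent_matrix(dataset)
  if (anyNA(pct)) stop("zero-coverage sites present; apply filter_coverage()")
  y <- pct[, grp == "young", drop = FALSE]
  a <- pct[, grp == "APA", drop = FALSE]
  ny <- ncol(y); na <- ncol(a)
  my <- rowMeans(y); ma <- rowMeans(a)
  vy <- row_vars(y); va <- row_vars(a)
  if (var_equal) {
    sp2 <- ((ny - 1) * vy + (na - 1) * va) / (ny + na - 2)
    se <- sqrt(sp2 * (1 / ny + 1 / na))
    df <- rep(ny + na - 2, length(se))
  } else {
    se <- sqrt(vy / ny + va / na)
    df <- (vy / ny + va / na)^2 /
      ((vy / ny)^2 / (ny - 1) + (va / na)^2 / (na - 1))
  }
  tstat <- (ma - my) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- !is.finite(se) | se == 0
  p[degen] <- ifelse(abs(ma - my)[degen] < 1e-12, 1, 0)
  finish_site_results(
    data.frame(chrom = dataset$sites$chrom, pos = dataset$sites$pos,
               mean_young = my, mean_apa = ma, delta = ma - my,
               p_value = p),
    alpha)
}

#' Per-CpG Fisher exact test on pooled counts
#'
#' The blastocyst-style design: methylated/unmethylated read counts are
#' pooled across samples within each group, giving one 2x2 table
#' (group x methylation state) per site, tested with the two-sided Fisher
#' exact test. Group means and the delta are still computed from per-sample
#' percentages so that both designs report comparable effect sizes.
#'
#' @inheritParams test_sites_ttest
#' @return As [test_sites_ttest()].
#' @export
test_sites_fisher <- function(dataset, alpha = 0.05) {
  grp <- dataset$samples$group
  pct <- methylation_percent_matrix(dataset)
  if (anyNA(pct)) stop("zero-coverage sites present; apply filter_coverage()")
  my <- rowMeans(pct[, grp == "young", drop = FALSE])
  ma <- rowMeans(pct[, grp == "APA", drop = FALSE])
  m_y <- rowSums(dataset$meth[, grp == "young", drop = FALSE])
  u_y <- rowSums(dataset$unmeth[, grp == "young", drop = FALSE])
  m_a <- rowSums(dataset$meth[, grp == "APA", drop = FALSE])
  u_a <- rowSums(dataset$unmeth[, grp == "APA", drop = FALSE])
  p <- vapply(seq_along(m_y), function(i) {
    stats::fisher.test(matrix(c(m_y[i], u_y[i], m_a[i], u_a[i]), 2))$p.value
  }, numeric(1))
  finish_site_results(
    data.frame(chrom = dataset$sites$chrom, pos = dataset$sites$pos,
               mean_young = my, mean_apa = ma, delta = ma - my,
               p_value = p),
    alpha)
}

#' Per-probe t-test on a beta matrix
#'
#' Array analogue of [test_sites_ttest()]: Welch t-test on beta values
#' between the two groups; the reported delta is on the percent scale,
#' `100 * (mean beta group2 - mean beta group1)`.
#'
#' @param bm A `BetaMatrix` with exactly two group labels.
#' @param alpha Significance threshold (default .05).
#' @return `SiteTestResult` data.frame keyed by probe coordinates.
#' @export
test_probes_ttest <- function(bm, alpha = 0.05) {
  grp <- bm$samples$group
  lev <- unique(grp)
  if (length(lev) != 2) stop("beta matrix must have exactly two groups")
  # align with the package convention: 'young'-style reference first
  if ("young" %in% lev) lev <- c("young", setdiff(lev, "young"))
  g1 <- bm$beta[, grp == lev[1], drop = FALSE]
  g2 <- bm$beta[, grp == lev[2], drop = FALSE]
  if (ncol(g1) < 2 || ncol(g2) < 2) stop("t-test requires >= 2 samples per group")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- row_vars(g1); v2 <- row_vars(g2)
  n1 <- ncol(g1); n2 <- ncol(g2)
  se <- sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- (m2 - m1) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- !is.finite(se) | se == 0
  p[degen] <- ifelse(abs(m2 - m1)[degen] < 1e-12, 1, 0)
  finish_site_results(
    data.frame(chrom = bm$probes$chrom, pos = bm$probes$pos,
               mean_young = 100 * m1, mean_apa = 100 * m2,
               delta = 100 * (m2 - m1), p_value = p),
    alpha)
}

#' Write per-site test results as TSV
#' @param results A `SiteTestResult` data.frame.
#' @param path Output path.
#' @export
write_site_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
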