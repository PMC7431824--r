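#' Hierarchical clustering of DMR member CpGs
#'
#' Rows are the per-sample methylation percentages of every DMR member
#' CpG, z-scored per row (so a positive score is hypermethylation relative
#' to the site mean); constant rows are dropped with a warning. Samples
#' are clustered on correlation distance (1 - Pearson by default,
#' 1 - Spearman with `method = "spearman"`) with average linkage, and the
#' two-group cut labels are returned.
#'
#' @param dataset A `MethylationDataset` (filtered for coverage).
#' @param dmrs Output of [call_dmrs()].
#' @param method Correlation flavour: `"pearson"` (default) or
#'   `"spearman"`.
#' @return List of class `ClusterResult`: `z` (CpGs x samples), `hclust`,
#'   `labels` (two-group cut, named by sample).
#' @export
cluster_dmr_cpgs <- function(dataset, dmrs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(dataset$samples) >= 2)
  keys <- paste(dataset$sites$chrom, dataset$sites$pos)
  member_keys <- unlist(lapply(seq_len(nrow(dmrs)), function(i) {
    paste(dmrs$chrom[i], dmrs$members[[i]])
  }))
  rows <- which(keys %in% member_keys)
  if (length(rows) < 2) stop("need >= 2 DMR member CpGs to cluster")
  pct <- methylation_percent_matrix(dataset)[rows, , drop = FALSE]
  sds <- apply(pct, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant CpG row(s) dropped before z-scoring")
    pct <- pct[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(pct) < 2) stop("fewer than 2 variable DMR member CpGs")
  }
  z <- (pct - rowMeans(pct)) / sds
  d <- as.dist(1 - cor(z, method = method))
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = 2)
  structure(list(z = z, hclust = hc,
                 labels = setNames(labels, dataset$samples$sample_id)),
            class = "ClusterResult")
}

#' Simple linear regression of methylation on age
#'
#' Ordinary least squares of per-sample methylation percentage on age in
#' years; the association-with-aging model used on validation cohorts.
#'
#' @param percent Numeric methylation percentages, one per sample.
#' @param age Ages in years (>= 3 samples, non-constant).
#' @return List of class `RegressionFit`: `slope` (percent per year),
#'   `intercept`, `r_squared`, `p_value` (two-sided on the slope).
#' @export
regress_meth_on_age <- function(percent, age) {
  stopifnot(length(percent) == length(age))
  if (length(age) < 3) stop("regression requires >= 3 samples")
  if (sd(age) == 0) stop("age is constant; slope undefined")
  fit <- lm(percent ~ age)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) {
    1  # zero-residual or degenerate fit: fall back to exact-fit convention
  } else sm$coefficients[2, 4]
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p),
            class = "RegressionFit")
}

#' Two-group comparison by t-test and Mann-Whitney U
#'
#' Returns both two-sided p-values; ties and identical groups resolve to
#' p = 1 (no-signal convention). The Mann-Whitney test uses the exact
#' distribution when both groups have <= 12 observations and no ties, the
#' normal approximation with tie correction otherwise.
#'
#' @param values_young,values_apa Numeric vectors, >= 2 each.
#' @return Named list: `t_p`, `mannwhitney_p`.
#' @export
compare_groups <- function(values_young, values_apa) {
  stopifnot(length(values_young) >= 2, length(values_apa) >= 2)
  if (sd(values_young) == 0 && sd(values_apa) == 0) {
    t_p <- if (mean(values_young) == mean(values_apa)) 1 else 0
  } else {
    t_p <- t.test(values_apa, values_young)$p.value
  }
  exact <- length(values_young) <= 12 && length(values_apa) <= 12
  w <- suppressWarnings(wilcox.test(values_apa, values_young, exact = exact,
                                    correct = TRUE))
  w_p <- w$p.value
  if (is.na(w_p)) w_p <- 1  # fully tied data carry no rank signal
  list(t_p = t_p, mannwhitney_p = w_p)
}

#' Reanalyze a 450K-style beta matrix through the DMR pipeline
#'
#' Array adapter: per-probe two-sided Welch t-test on beta values between
#' groups, deltas on the percent scale, then the standard windowed DMR
#' caller in array mode (>= 2 significant probes per region by default;
#' the 10-point mean-difference filter is retained unless overridden).
#' Probes lacking coordinates are dropped and counted.
#'
#' @param bm A `BetaMatrix`.
#' @param alpha Per-probe significance threshold (default .05).
#' @param config A [dmr_config()]; defaults to array mode
#'   (`min_cpgs = 2`).
#' @return List: `dmrs`, `site_results`, `n_dropped_probes`.
#' @export
reanalyze_beta_matrix <- function(bm, alpha = 0.05,
                                  config = dmr_config(min_cpgs = 2)) {
  has_coord <- !is.na(bm$probes$chrom) & !is.na(bm$probes$pos)
  n_dropped <- sum(!has_coord)
  if (n_dropped) {
    bm <- beta_matrix(bm$probes[has_coord, , drop = FALSE],
                      bm$beta[has_coord, , drop = FALSE],
                      bm$samples$sample_id, bm$samples$group)
  }
  res <- test_probes_ttest(bm, alpha = alpha)
  config$alpha <- alpha
  dmrs <- call_dmrs(res, config)
  list(dmrs = dmrs, site_results = res, n_dropped_probes = n_dropped)
}
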