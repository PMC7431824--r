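mk_dmr_for <- function(ds) {
  # one DMR covering every site in the dataset
  d <- data.frame(chrom = ds$sites$chrom[1], start = min(ds$sites$pos),
                  end = max(ds$sites$pos) + 1L, direction = "hyper",
                  n_sig_cpgs = nrow(ds$sites), mean_delta = 20,
                  width = diff(range(ds$sites$pos)) + 1L)
  d$members <- list(ds$sites$pos)
  class(d) <- c("DMR", class(d))
  d
}

test_that("clustering distance behaves at the correlation extremes", {
  set.seed(51)
  base <- matrix(runif(40, 20, 80), 10, 4)
  pct <- cbind(base[, 1], base[, 1], base[, 2:4])  # duplicated column
  ds <- dataset_from_pct("chr1", as.integer(seq(100, by = 50, length.out = 10)),
                         pct_young = pct[, 1:3], pct_apa = pct[, 4:5],
                         reads = 1e6)
  cl <- cluster_dmr_cpgs(ds, mk_dmr_for(ds))
  dist_mat <- as.matrix(as.dist(1 - cor(cl$z)))
  expect_lt(dist_mat[1, 2], 1e-10)

  # anti-correlated pair: distance 2
  v <- seq(10, 90, length.out = 10)
  pct2 <- cbind(v, rev(v), v, rev(v))
  ds2 <- dataset_from_pct("chr1", as.integer(seq(100, by = 50, length.out = 10)),
                          pct_young = pct2[, 1:2], pct_apa = pct2[, 3:4],
                          reads = 1e6)
  cl2 <- cluster_dmr_cpgs(ds2, mk_dmr_for(ds2))
  d2 <- as.matrix(as.dist(1 - cor(cl2$z)))
  expect_equal(d2[1, 2], 2, tolerance = 1e-10)

  # z rows are standardized and constant rows dropped with a warning
  expect_true(all(abs(rowMeans(cl$z)) < 1e-10))
  expect_true(all(abs(apply(cl$z, 1, sd) - 1) < 1e-10))
  pct3 <- rbind(rep(50, 5), pct[1:9, ])
  ds3 <- dataset_from_pct("chr1", as.integer(seq(100, by = 50, length.out = 10)),
                          pct_young = pct3[, 1:3], pct_apa = pct3[, 4:5],
                          reads = 1e6)
  expect_warning(cluster_dmr_cpgs(ds3, mk_dmr_for(ds3)), "constant")
})

test_that("clustering is invariant to per-CpG affine rescaling", {
  set.seed(52)
  pct <- matrix(runif(60, 10, 90), 10, 6)
  pos <- as.integer(seq(100, by = 50, length.out = 10))
  ds <- dataset_from_pct("chr1", pos, pct[, 1:3], pct[, 4:6], reads = 1e8)
  cl <- cluster_dmr_cpgs(ds, mk_dmr_for(ds))
  scaled <- pct * 0.5 + 10  # affine per-site transform (same for all rows)
  dss <- dataset_from_pct("chr1", pos, scaled[, 1:3], scaled[, 4:6],
                          reads = 1e8)
  cls <- cluster_dmr_cpgs(dss, mk_dmr_for(dss))
  expect_equal(cls$z, cl$z, tolerance = 1e-5)
  expect_equal(mclust::adjustedRandIndex(cls$labels, cl$labels), 1)
})

test_that("spiked cohorts cluster into their two groups", {
  recovered <- vapply(1:10, function(s) {
    cfg <- sim_config(n_chroms = 1, chrom_length = 4e5, n_islands = 10,
                      cpgs_per_island = 6, background_cpg_rate = 1e-4,
                      n_spiked_hyper = 3, n_spiked_hypo = 3, seed = 600 + s)
    sim <- simulate_counts(simulate_genome(cfg), cfg)
    ds <- filter_coverage(sim$dataset)
    dmrs <- call_dmrs(test_sites_ttest(ds))
    cl <- cluster_dmr_cpgs(ds, dmrs)
    mclust::adjustedRandIndex(cl$labels, ds$samples$group)
  }, numeric(1))
  expect_gte(mean(recovered == 1), 0.9)
})

test_that("age regression returns OLS slope, R-squared and p", {
  f <- regress_meth_on_age(c(40, 35, 30), c(50, 55, 60))
  expect_equal(f$slope, -1)
  expect_equal(f$intercept, 90)
  expect_equal(f$r_squared, 1)
  expect_error(regress_meth_on_age(c(1, 2, 3), c(50, 50, 50)), "constant")
  expect_error(regress_meth_on_age(c(1, 2), c(50, 60)), ">= 3")

  # closed-form normal equations oracle
  set.seed(53)
  for (i in 1:20) {
    age <- runif(10, 50, 64)
    y <- runif(10, 20, 80)
    fit <- regress_meth_on_age(y, age)
    beta <- cov(age, y) / var(age)
    expect_equal(fit$slope, beta, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y) - beta * mean(age), tolerance = 1e-10)
  }
})

test_that("null age regressions are calibrated", {
  set.seed(54)
  p <- vapply(1:4000, function(i) {
    regress_meth_on_age(runif(18, 20, 80), runif(18, 25, 64))$p_value
  }, numeric(1))
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
})

test_that("compare_groups honours tie conventions and exact ranks", {
  same <- compare_groups(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$t_p, 1)
  expect_equal(same$mannwhitney_p, 1)

  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$mannwhitney_p, 0.1)  # exact two-sided 2/C(6,3)

  # rank invariance under a monotone transform of both groups
  a <- c(2, 5, 9, 13); b <- c(3, 7, 20, 40)
  expect_equal(compare_groups(a, b)$mannwhitney_p,
               compare_groups(log(a), log(b))$mannwhitney_p)
})

test_that("beta-matrix reanalysis calls the spiked region in array mode", {
  # 4 spiked probes at delta -0.3, separated from flanking probes
  set.seed(55)
  n_y <- 6; n_a <- 6
  pos <- as.integer(c(1000, 1200, 1400, 1600, 9000, 20000))
  probes <- data.frame(probe_id = sprintf("cg%02d", seq_along(pos)),
                       chrom = "chr1", pos = pos)
  base <- c(0.6, 0.6, 0.6, 0.6, 0.5, 0.5)
  beta_y <- matrix(rep(base, n_y), ncol = n_y) +
    matrix(rnorm(length(pos) * n_y, 0, 0.02), ncol = n_y)
  beta_a <- matrix(rep(base + c(-0.3, -0.3, -0.3, -0.3, 0, 0), n_a),
                   ncol = n_a) +
    matrix(rnorm(length(pos) * n_a, 0, 0.02), ncol = n_a)
  bm <- beta_matrix(probes, pmin(pmax(cbind(beta_y, beta_a), 0), 1),
                    c(sprintf("y%d", 1:n_y), sprintf("a%d", 1:n_a)),
                    c(rep("young", n_y), rep("APA", n_a)))
  out <- reanalyze_beta_matrix(bm)
  expect_equal(nrow(out$dmrs), 1)
  expect_equal(out$dmrs$direction, "hypo")
  expect_equal(out$dmrs$start, 1000L)
  expect_equal(out$dmrs$end, 1601L)
  expect_equal(out$dmrs$n_sig_cpgs, 4L)

  # a 2-probe cluster is a DMR only in array mode (min_cpgs = 2)
  pos2 <- as.integer(c(1000, 1200, 50000))
  probes2 <- data.frame(probe_id = sprintf("cg%02d", 1:3), chrom = "chr1",
                        pos = pos2)
  b_y <- matrix(0.6, 3, n_y) + rnorm(3 * n_y, 0, 0.02)
  b_a <- matrix(c(0.3, 0.3, 0.6), 3, n_a) + rnorm(3 * n_a, 0, 0.02)
  bm2 <- beta_matrix(probes2, pmin(pmax(cbind(b_y, b_a), 0), 1),
                     c(sprintf("y%d", 1:n_y), sprintf("a%d", 1:n_a)),
                     c(rep("young", n_y), rep("APA", n_a)))
  expect_equal(nrow(reanalyze_beta_matrix(bm2)$dmrs), 1)
  expect_equal(nrow(reanalyze_beta_matrix(
    bm2, config = dmr_config(min_cpgs = 3))$dmrs), 0)
})

test_that("count and beta paths agree on noiseless shared data", {
  # identical percentages fed through both routes call identical DMRs
  set.seed(56)
  pos <- as.integer(seq(1000, by = 150, length.out = 12))
  pct_y <- matrix(rep(60, 12 * 4), ncol = 4) + rnorm(48, 0, 1)
  pct_a <- matrix(rep(c(rep(30, 5), rep(60, 7)), 4), ncol = 4) +
    rnorm(48, 0, 1)
  reads <- 1e6
  ds <- dataset_from_pct("chr1", pos, pct_y, pct_a, reads = reads)
  pct_obs <- methylation_percent_matrix(ds)
  bm <- beta_matrix(data.frame(probe_id = sprintf("cg%02d", 1:12),
                               chrom = "chr1", pos = pos),
                    pct_obs / 100, ds$samples$sample_id, ds$samples$group)
  cfg <- dmr_config(min_cpgs = 3)
  from_counts <- call_dmrs(test_sites_ttest(ds), cfg)
  from_beta <- reanalyze_beta_matrix(bm, config = cfg)$dmrs
  expect_equal(from_counts$start, from_beta$start)
  expect_equal(from_counts$end, from_beta$end)
  expect_equal(from_counts$direction, from_beta$direction)
  expect_equal(from_counts$mean_delta, from_beta$mean_delta, tolerance = 1e-6)
})
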