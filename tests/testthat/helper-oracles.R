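# Independent oracles and fixture builders shared across test files.
# Each oracle deliberately re-derives its quantity from first principles,
# on a different code path from the package implementation.

# two-sided Fisher exact p by exhaustive enumeration of all tables with
# the observed margins, minimum-likelihood rule
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b
  n <- a + b + c + d
  k1 <- a + c
  lo <- max(0, k1 - (n - r1))
  hi <- min(r1, k1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, n - r1, k1)
  p_obs <- dhyper(a, r1, n - r1, k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the literal step-up definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- pmin(adj, 1)
  q
}

# KDE by a scalar double loop with a hand-written Silverman bandwidth
kde_oracle <- function(sites, grid, adjust = 0.2) {
  n <- length(sites)
  sig <- sd(sites)
  iqr <- unname(diff(quantile(sites, c(0.25, 0.75))))
  bw <- adjust * 0.9 * min(sig, iqr / 1.34) * n^(-1 / 5)
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    acc <- 0
    for (s in sites) {
      z <- (grid[i] - s) / bw
      acc <- acc + exp(-z^2 / 2) / sqrt(2 * pi)
    }
    out[i] <- acc / (n * bw)
  }
  out
}

# brute-force DMR caller: significant sites are connected whenever their
# pairwise gap is <= lambda (full O(n^2) adjacency), maximal clusters are
# graph components, then per-direction filters applied — no cumsum shortcut
dmr_oracle <- function(site_results, lambda_bp = 1000, min_cpgs = 3,
                       min_delta = 10, alpha = 0.05) {
  sig <- site_results[site_results$p_value <= alpha &
                        site_results$delta != 0, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    n <- nrow(s)
    adj <- abs(outer(s$pos, s$pos, "-")) <= lambda_bp
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    for (cl in unique(comp)) {
      cs <- s[comp == cl, , drop = FALSE]
      for (dir in c("hyper", "hypo")) {
        mem <- cs[if (dir == "hyper") cs$delta > 0 else cs$delta < 0, ,
                  drop = FALSE]
        if (nrow(mem) >= min_cpgs &&
            abs(mean(mem$delta)) >= min_delta) {
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = min(mem$pos), end = max(mem$pos) + 1L,
            direction = dir, n_sig_cpgs = nrow(mem),
            mean_delta = mean(mem$delta))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_sig_cpgs = integer(0), mean_delta = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random SiteTestResult table on one or two chromosomes
random_site_results <- function(n, chroms = c("chrA", "chrB"),
                                span = 20000) {
  chrom <- sort(sample(chroms, n, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(span, sum(chrom == ch)))
  }))
  df <- data.frame(chrom = chrom, pos = pos,
                   mean_young = 50, mean_apa = 50,
                   delta = round(runif(n, -40, 40), 1),
                   p_value = runif(n)^2)
  df$significant <- df$p_value <= 0.05
  df$direction <- ifelse(!df$significant | df$delta == 0, "none",
                         ifelse(df$delta > 0, "hyper", "hypo"))
  df[order(df$chrom, df$pos), ]
}

# dataset built directly from percentage matrices at fixed coverage
dataset_from_pct <- function(chrom, pos, pct_young, pct_apa, reads = 100) {
  pct <- cbind(pct_young, pct_apa)
  meth <- round(pct / 100 * reads)
  unmeth <- reads - meth
  ids <- c(paste0("y", seq_len(ncol(pct_young))),
           paste0("a", seq_len(ncol(pct_apa))))
  methylation_dataset(data.frame(chrom = chrom, pos = pos), meth, unmeth,
                      ids, c(rep("young", ncol(pct_young)),
                             rep("APA", ncol(pct_apa))))
}

small_sim_config <- function(seed, ...) {
  args <- list(n_chroms = 1, chrom_length = 2e5, n_islands = 4,
               cpgs_per_island = 8, background_cpg_rate = 2e-4,
               n_spiked_hyper = 1, n_spiked_hypo = 1,
               n_genes_per_chrom = 10, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
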