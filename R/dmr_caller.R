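#' DMR caller configuration
#'
#' Parameters of the windowed directional DMR rule: significant CpGs are
#' clustered per chromosome by cutting wherever the gap between consecutive
#' significant sites exceeds `lambda_bp`; within a cluster, each direction
#' independently forms a DMR when it has at least `min_cpgs` significant
#' CpGs whose mean delta is at least `min_mean_abs_delta` in absolute value.
#' `kernel_C` records the kernel scaling constant used by kernel-based
#' region callers for provenance; the windowed rule here does not use it.
#'
#' @param lambda_bp Maximum gap between member CpGs, bp (default 1000).
#' @param min_cpgs Minimum significant CpGs per DMR (default 3; array-style
#'   reanalyses conventionally use 2).
#' @param min_mean_abs_delta Minimum absolute mean methylation difference,
#'   percentage points (default 10).
#' @param alpha Per-CpG significance threshold (default .05).
#' @param mean_over Average the delta over the DMR's own-direction
#'   significant members (`"significant"`, default) or over all tested CpGs
#'   inside the span (`"all"`).
#' @param kernel_C Recorded, unused (default 75).
#' @return List of class `dmr_config`.
#' @export
dmr_config <- function(lambda_bp = 1000, min_cpgs = 3,
                       min_mean_abs_delta = 10, alpha = 0.05,
                       mean_over = c("significant", "all"),
                       kernel_C = 75) {
  stopifnot(lambda_bp > 0, min_cpgs >= 2, min_mean_abs_delta >= 0,
            alpha >= 0, alpha <= 1)
  mean_over <- match.arg(mean_over)
  structure(list(lambda_bp = lambda_bp, min_cpgs = min_cpgs,
                 min_mean_abs_delta = min_mean_abs_delta, alpha = alpha,
                 mean_over = mean_over, kernel_C = kernel_C),
            class = "dmr_config")
}

#' Call directional differentially methylated regions
#'
#' Implements the windowed sliding rule: (1) keep significant sites
#' (`p <= alpha`, nonzero delta); (2) per chromosome, partition them into
#' clusters by cutting whenever the gap to the previous significant site
#' exceeds `lambda_bp`; (3) within each cluster and for each direction
#' independently, the significant sites of that sign form a DMR if there
#' are at least `min_cpgs` of them and the absolute mean of their deltas is
#' at least `min_mean_abs_delta`; a cluster can thus emit at most one
#' hypermethylated and one hypomethylated DMR. A DMR spans its member CpGs
#' half-open: `[first member, last member + 1)`.
#'
#' @param site_results `SiteTestResult` data.frame sorted by (chrom, pos).
#' @param config A [dmr_config()].
#' @return data.frame of class `DMR` with columns `chrom`, `start`, `end`,
#'   `direction`, `n_sig_cpgs`, `mean_delta`, `width`, and list-column
#'   `members` of member positions.
#' @export
call_dmrs <- function(site_results, config = dmr_config()) {
  stopifnot(inherits(config, "dmr_config"))
  ord <- order(site_results$chrom, site_results$pos)
  if (any(ord != seq_len(nrow(site_results)))) {
    stop("site results must be sorted by (chrom, pos)")
  }
  sig <- site_results[site_results$p_value <= config$alpha &
                        site_results$delta != 0, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    gaps <- diff(s$pos)
    cluster <- cumsum(c(1L, as.integer(gaps > config$lambda_bp)))
    for (cl in unique(cluster)) {
      cs <- s[cluster == cl, , drop = FALSE]
      for (dir in c("hyper", "hypo")) {
        mem <- cs[if (dir == "hyper") cs$delta > 0 else cs$delta < 0, ,
                  drop = FALSE]
        if (nrow(mem) < config$min_cpgs) next
        if (config$mean_over == "significant") {
          md <- mean(mem$delta)
        } else {
          span <- site_results$chrom == ch &
            site_results$pos >= min(mem$pos) &
            site_results$pos <= max(mem$pos)
          md <- mean(site_results$delta[span])
        }
        if (abs(md) < config$min_mean_abs_delta) next
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(mem$pos), end = max(mem$pos) + 1L,
          direction = dir, n_sig_cpgs = nrow(mem), mean_delta = md,
          width = max(mem$pos) + 1L - min(mem$pos))
        out[[length(out)]]$members <- list(mem$pos)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               direction = character(0), n_sig_cpgs = integer(0),
               mean_delta = numeric(0), width = integer(0),
               members = I(list()))
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("DMR", class(res))
  res
}

#' Summarize called DMRs per direction
#'
#' Tallies, for hypermethylated and hypomethylated DMRs separately: total
#' DMRs, total significant member CpGs, mean and range of CpGs per DMR,
#' mean and range of width in bp.
#'
#' @param dmrs Output of [call_dmrs()].
#' @return data.frame with one row per direction.
#' @export
summarize_dmrs <- function(dmrs) {
  do.call(rbind, lapply(c("hyper", "hypo"), function(dir) {
    d <- dmrs[dmrs$direction == dir, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(direction = dir, n_dmrs = 0L, n_sig_cpgs = 0L,
                        mean_cpgs = NA_real_, min_cpgs = NA_integer_,
                        max_cpgs = NA_integer_, mean_width = NA_real_,
                        min_width = NA_integer_, max_width = NA_integer_))
    }
    data.frame(direction = dir, n_dmrs = nrow(d),
               n_sig_cpgs = sum(d$n_sig_cpgs),
               mean_cpgs = mean(d$n_sig_cpgs),
               min_cpgs = min(d$n_sig_cpgs), max_cpgs = max(d$n_sig_cpgs),
               mean_width = mean(d$width),
               min_width = min(d$width), max_width = max(d$width))
  }))
}

#' Write DMRs as BED6+ (name, score = n_sig_cpgs, direction, mean_delta)
#' @param dmrs Output of [call_dmrs()].
#' @param path Output path.
#' @export
write_dmrs <- function(dmrs, path) {
  df <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                   name = sprintf("DMR_%04d", seq_len(nrow(dmrs))),
                   score = dmrs$n_sig_cpgs, strand = ".",
                   direction = dmrs$direction,
                   mean_delta = sprintf("%.4f", dmrs$mean_delta),
                   width = dmrs$width)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
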