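#' Construct a methylation count dataset
#'
#' The central container of the package: CpG sites by samples matrices of
#' methylated / unmethylated read counts with per-sample group labels
#' (`"young"` control vs `"APA"` advanced paternal age) and optional ages.
#' All coordinates are 0-based half-open; a CpG site is a single base.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based bp).
#' @param meth,unmeth Integer matrices, sites x samples, of methylated and
#'   unmethylated read counts.
#' @param sample_id Character vector of sample names (column order).
#' @param group Factor/character per sample, levels `young` and `APA`.
#' @param age Optional numeric per-sample age in years.
#' @return An object of class `MethylationDataset`.
#' @export
methylation_dataset <- function(sites, meth, unmeth, sample_id, group,
                                age = NULL) {
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos))
  n_sites <- nrow(sites)
  n_samp <- length(sample_id)
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  stopifnot(nrow(meth) == n_sites, nrow(unmeth) == n_sites,
            ncol(meth) == n_samp, ncol(unmeth) == n_samp)
  if (any(meth < 0) || any(unmeth < 0)) stop("negative read counts")
  group <- as.character(group)
  if (!all(group %in% c("young", "APA"))) {
    stop("group labels must be 'young' or 'APA'")
  }
  if (length(unique(group)) < 2) stop("need at least one sample per group")
  ord <- order(sites$chrom, sites$pos)
  if (any(ord != seq_len(n_sites))) {
    sites <- sites[ord, , drop = FALSE]
    meth <- meth[ord, , drop = FALSE]
    unmeth <- unmeth[ord, , drop = FALSE]
  }
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("duplicate CpG sites")
  }
  rownames(sites) <- NULL
  dimnames(meth) <- dimnames(unmeth) <- list(NULL, sample_id)
  if (!is.null(age)) stopifnot(length(age) == n_samp)
  structure(
    list(sites = sites, meth = meth, unmeth = unmeth,
         samples = data.frame(sample_id = as.character(sample_id),
                              group = group,
                              age = if (is.null(age)) NA_real_ else age)),
    class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat("MethylationDataset:", nrow(x$sites), "CpG sites x",
      nrow(x$samples), "samples (",
      sum(x$samples$group == "young"), "young /",
      sum(x$samples$group == "APA"), "APA )\n")
  invisible(x)
}

#' Per-sample methylation percentage matrix
#'
#' @param dataset A `MethylationDataset`.
#' @return Numeric matrix (sites x samples) of percentages; `NaN` where a
#'   sample has zero reads at a site.
#' @export
methylation_percent_matrix <- function(dataset) {
  100 * dataset$meth / (dataset$meth + dataset$unmeth)
}

#' Read a Bismark-style coverage file for one sample
#'
#' Expects six tab-separated columns: chromosome, start (1-based), end,
#' methylation percentage, methylated count, unmethylated count. Positions
#' are converted to the package-wide 0-based convention at read time. The
#' percentage column is cross-checked against the counts (tolerance 0.1)
#' whenever the site has any reads; zero-coverage rows are retained with
#' `covered = FALSE`.
#'
#' @param path Path to the coverage TSV (no header).
#' @param sample_id Sample name attached to the result.
#' @return data.frame with columns `chrom`, `pos`, `n_meth`, `n_unmeth`,
#'   `pct`, `covered` and attribute `sample_id`.
#' @export
read_coverage_file <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty coverage file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 6L
  if (any(!ncol_ok)) {
    stop("line ", which(!ncol_ok)[1], " unparseable (expected 6 columns)")
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  start1 <- suppressWarnings(as.numeric(m[, 2]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  n_meth <- suppressWarnings(as.numeric(m[, 5]))
  n_unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start1) | is.na(pct) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad)) stop("line ", bad[1], " unparseable")
  if (any(n_meth < 0 | n_unmeth < 0)) {
    stop("line ", which(n_meth < 0 | n_unmeth < 0)[1], ": negative count")
  }
  total <- n_meth + n_unmeth
  recomputed <- ifelse(total > 0, 100 * n_meth / total, 0)
  mism <- which(total > 0 & abs(recomputed - pct) > 0.1)
  if (length(mism)) {
    stop("line ", mism[1], ": %meth column disagrees with counts")
  }
  out <- data.frame(chrom = m[, 1],
                    pos = as.integer(start1) - 1L,
                    n_meth = as.integer(n_meth),
                    n_unmeth = as.integer(n_unmeth),
                    pct = recomputed,
                    covered = total > 0)
  if (any(out$pos < 0)) stop("coverage positions must be >= 1 (1-based)")
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a per-sample coverage table in Bismark dialect
#'
#' Inverse of [read_coverage_file()]: 1-based inclusive single-base rows.
#'
#' @param counts data.frame as returned by [read_coverage_file()].
#' @param path Output path.
#' @export
write_coverage_file <- function(counts, path) {
  total <- counts$n_meth + counts$n_unmeth
  pct <- ifelse(total > 0, 100 * counts$n_meth / total, 0)
  df <- data.frame(counts$chrom, counts$pos + 1L, counts$pos + 1L,
                   sprintf("%.6g", pct), counts$n_meth, counts$n_unmeth)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge per-sample coverage tables into a dataset
#'
#' Applies the minimum read-count filter: a CpG site is retained only when
#' every sample (in both groups) has `n_meth + n_unmeth >= min_coverage`
#' reads there. The default of 5 reads gives a theoretical resolution for
#' methylation-difference detection of 100 / 5 = 20 percent.
#'
#' @param sample_counts Named list of per-sample data.frames from
#'   [read_coverage_file()].
#' @param group Named character vector (`young`/`APA`) keyed by sample name,
#'   or unnamed in the same order as `sample_counts`.
#' @param min_coverage Minimum reads per site per sample (default 5).
#' @param age Optional named numeric vector of ages.
#' @return A `MethylationDataset` of the sites passing the filter everywhere.
#' @export
merge_samples <- function(sample_counts, group, min_coverage = 5, age = NULL) {
  stopifnot(length(sample_counts) >= 2, min_coverage >= 1)
  ids <- names(sample_counts)
  if (is.null(ids)) stop("sample_counts must be a named list")
  if (!is.null(names(group))) group <- group[ids]
  if (!is.null(age) && !is.null(names(age))) age <- age[ids]
  keys <- lapply(sample_counts, function(x) paste(x$chrom, x$pos, sep = ":"))
  common <- Reduce(intersect, keys)
  if (length(common)) {
    meth <- sapply(seq_along(sample_counts), function(i) {
      sample_counts[[i]]$n_meth[match(common, keys[[i]])]
    })
    unmeth <- sapply(seq_along(sample_counts), function(i) {
      sample_counts[[i]]$n_unmeth[match(common, keys[[i]])]
    })
    meth <- matrix(meth, ncol = length(sample_counts))
    unmeth <- matrix(unmeth, ncol = length(sample_counts))
    keep <- rowSums(meth + unmeth >= min_coverage) == ncol(meth)
  } else keep <- logical(0)
  if (!any(keep)) stop("no sites pass coverage in all samples")
  parts <- strsplit(common[keep], ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)))
  methylation_dataset(sites, meth[keep, , drop = FALSE],
                      unmeth[keep, , drop = FALSE],
                      sample_id = ids, group = group, age = age)
}

#' Read a BED3/BED4/BED6 file of genomic intervals
#'
#' @param path BED path (0-based half-open, no header).
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name` and `strand`.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]))
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  if (ncol(x) >= 6) out$strand <- as.character(x[[6]])
  validate_intervals(out, paste0("BED file ", basename(path)))
  out
}

#' Write intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, intersect(c("chrom", "start", "end", "name"),
                                names(intervals)), drop = FALSE]
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a UCSC cytoBand table
#'
#' Expects the cytoBand.txt dialect: chrom, start, end, band, stain. Band
#' names are normalized to the conventional `19p13.3` style (chromosome
#' without the `chr` prefix followed by the band label).
#'
#' @param path Path to the table.
#' @return data.frame `chrom`, `start`, `end`, `name` (e.g. `"19p13.3"`),
#'   `band`, `stain`.
#' @export
read_cytobands <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("cytoband table needs >= 4 columns")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    band = as.character(x[[4]]),
                    stain = if (ncol(x) >= 5) as.character(x[[5]]) else NA)
  validate_intervals(out, "cytoband table")
  dup <- duplicated(paste(out$chrom, out$band))
  if (any(dup)) {
    stop("duplicate band name '", out$band[dup][1], "' on ",
         out$chrom[dup][1])
  }
  out$name <- paste0(sub("^chr", "", out$chrom), out$band)
  out[, c("chrom", "start", "end", "name", "band", "stain")]
}

#' Write a cytoband table in UCSC dialect
#' @param bands data.frame from [read_cytobands()] or the simulator.
#' @param path Output path.
#' @export
write_cytobands <- function(bands, path) {
  stain <- if ("stain" %in% names(bands)) bands$stain else "gneg"
  stain[is.na(stain)] <- "gneg"
  write.table(data.frame(bands$chrom, bands$start, bands$end, bands$band,
                         stain),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat-like TSV
#'
#' Columns: symbol, chrom, strand, txStart, txEnd (0-based half-open).
#' Symbols are upper-cased so downstream set operations are case-stable.
#' The transcription start site is strand-aware: `start` on `+`, `end - 1`
#' on `-`.
#'
#' @param path Path to the gene table (no header).
#' @return data.frame `symbol`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_models <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 5) stop("gene table needs 5 columns (symbol chrom strand start end)")
  out <- data.frame(symbol = toupper(as.character(x[[1]])),
                    chrom = as.character(x[[2]]),
                    strand = as.character(x[[3]]),
                    start = as.integer(x[[4]]),
                    end = as.integer(x[[5]]))
  if (!all(out$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  validate_intervals(out, "gene table")
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out
}

#' Write gene models as the refFlat-like TSV read by [read_gene_models()]
#' @param genes data.frame with `symbol`, `chrom`, `strand`, `start`, `end`.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes[, c("symbol", "chrom", "strand", "start", "end")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#' @param path Path to the list.
#' @return Character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  unique(toupper(trimws(x[nzchar(trimws(x))])))
}

#' Write a gene list
#' @param symbols Character vector.
#' @param path Output path.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(sort(unique(toupper(symbols))), path)
  invisible(path)
}

#' Construct a 450K-style beta-value matrix
#'
#' @param probes data.frame `probe_id`, `chrom`, `pos` (0-based bp).
#' @param beta Numeric matrix probes x samples with values in \[0, 1\].
#' @param sample_id Character sample names.
#' @param group Per-sample labels (two levels; conventionally group 1 is the
#'   reference and deltas are group2 - group1).
#' @return Object of class `BetaMatrix`.
#' @export
beta_matrix <- function(probes, beta, sample_id, group) {
  beta <- as.matrix(beta)
  probes <- data.frame(probe_id = as.character(probes$probe_id),
                       chrom = as.character(probes$chrom),
                       pos = as.integer(probes$pos))
  stopifnot(nrow(beta) == nrow(probes), ncol(beta) == length(sample_id))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values outside [0,1]")
  if (anyDuplicated(paste(probes$chrom, probes$pos))) {
    stop("duplicate probe positions")
  }
  ord <- order(probes$chrom, probes$pos)
  probes <- probes[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  rownames(probes) <- NULL
  dimnames(beta) <- list(probes$probe_id, sample_id)
  structure(list(probes = probes, beta = beta,
                 samples = data.frame(sample_id = as.character(sample_id),
                                      group = as.character(group))),
            class = "BetaMatrix")
}

#' Read a beta matrix from its probe-map and value TSVs
#'
#' @param probes_path TSV with header `probe_id chrom pos`.
#' @param beta_path TSV with header `probe_id` plus one column per sample.
#' @param group Named (by sample) or ordered group labels.
#' @return A `BetaMatrix`.
#' @export
read_beta_matrix <- function(probes_path, beta_path, group) {
  probes <- read.table(probes_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  vals <- read.table(beta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  ord <- match(probes$probe_id, vals[[1]])
  if (anyNA(ord)) stop("beta matrix missing probes listed in the probe map")
  ids <- colnames(m)
  if (!is.null(names(group))) group <- group[ids]
  beta_matrix(probes, m[ord, , drop = FALSE], ids, group)
}

#' Write a beta matrix as the TSV pair read by [read_beta_matrix()]
#' @param bm A `BetaMatrix`.
#' @param probes_path,beta_path Output paths.
#' @export
write_beta_matrix <- function(bm, probes_path, beta_path) {
  write.table(bm$probes, probes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  df <- data.frame(probe_id = bm$probes$probe_id, bm$beta,
                   check.names = FALSE)
  write.table(df, beta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(beta_path)
}
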