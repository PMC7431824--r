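#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a distinct sub-seed from a master seed; kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

#' Validate a table of genomic intervals
#'
#' Checks the 0-based half-open interval invariants used throughout the
#' package: non-empty chromosome names, `start >= 0`, `end > start`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid.
#' @keywords internal
#' @noRd
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom)))) {
    stop(what, ": empty chromosome name")
  }
  if (any(x$start < 0)) stop(what, ": negative start coordinate")
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(what, ": end <= start at line ", bad[1])
  }
  invisible(x)
}

# data.frame of intervals -> GRanges (0-based half-open -> IRanges 1-based)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# single positions (0-based) -> width-1 GRanges
pos_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

# row variances of a matrix without apply() overhead
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
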