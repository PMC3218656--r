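#' @useDynLib somaticSV, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats median rbinom runif rpois quantile setNames complete.cases
#' @importFrom utils head tail write.table read.table packageVersion
NULL

# Coordinates are 1-based inclusive everywhere inside the package (IRanges
# convention); BED/BEDPE writers convert to 0-based half-open on output.

BASES <- c("A", "C", "G", "T")

#' Derive a per-stage substream seed from a master seed
#'
#' Stage seeds are deterministic functions of the master seed so every stage
#' of a run can be reproduced in isolation. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 1009) %% 2147483629) + 1L
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

substr_safe <- function(x, start, end) {
  if (end < start) return("")
  substr(x, max(1L, start), end)
}

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) {  # longest common suffix length
  ra <- paste(rev(strsplit(a, "", fixed = TRUE)[[1]]), collapse = "")
  rb <- paste(rev(strsplit(b, "", fixed = TRUE)[[1]]), collapse = "")
  lcp_len(ra, rb)
}

# interval set helpers on data.frames with chrom/start/end (1-based inclusive)
as_iranges_by_chrom <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(list())
  split(IRanges::IRanges(start = df$start, end = df$end), df$chrom)
}

# TRUE for each (chrom, pos) lying within `slop` of any interval in mask
near_mask <- function(chrom, pos, mask, slop = 0L) {
  out <- logical(length(chrom))
  if (is.null(mask) || nrow(mask) == 0L) return(out)
  byc <- as_iranges_by_chrom(mask)
  for (ch in names(byc)) {
    sel <- chrom == ch
    if (!any(sel)) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    m <- IRanges::IRanges(
      start = pmax(1L, IRanges::start(byc[[ch]]) - slop),
      end = IRanges::end(byc[[ch]]) + slop
    )
    out[sel] <- IRanges::overlapsAny(q, m)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
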