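#' Build bins of approximately equal mappable sequence
#'
#' Divides each chromosome into bins holding about `target` bp of mappable
#' sequence, where mappable means outside the repeat and assembly-gap
#' masks. Bin genomic widths therefore vary: a bin overlapping a masked
#' region stretches until it has accumulated its quota of mappable bases.
#' Bins tile each chromosome without overlap; the terminal bin carries the
#' remainder and a chromosome with less than `target` mappable bp yields a
#' single bin flagged `undersized`.
#'
#' @param reference named character vector of chromosome sequences, or a
#'   named integer vector of chromosome lengths.
#' @param repeat_mask,gap_mask data.frames (chrom, start, end) or NULL.
#' @param target mappable bp per bin (default 15 kb).
#' @return data.frame: `chrom`, `start`, `end`, `mappable_bp`, `undersized`.
#' @export
build_mappable_bins <- function(reference, repeat_mask = NULL,
                                gap_mask = NULL, target = 15000L) {
  lens <- if (is.character(reference)) nchar(reference)
  else setNames(as.integer(reference), names(reference))
  stopifnot(!is.null(names(lens)))
  out <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    masked <- rbind(
      if (!is.null(repeat_mask) && nrow(repeat_mask))
        repeat_mask[repeat_mask$chrom == ch, c("start", "end")],
      if (!is.null(gap_mask) && nrow(gap_mask))
        gap_mask[gap_mask$chrom == ch, c("start", "end")])
    mir <- if (is.null(masked) || nrow(masked) == 0L) IRanges::IRanges()
    else IRanges::reduce(IRanges::IRanges(pmax(1L, masked$start),
                                          pmin(L, masked$end)))
    mappable <- IRanges::setdiff(IRanges::IRanges(1L, L), mir)
    w <- IRanges::width(mappable)
    total <- sum(w)
    if (total < target) {
      out[[ch]] <- data.frame(chrom = ch, start = 1L, end = L,
                              mappable_bp = total, undersized = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    n_full <- total %/% target
    cumw <- cumsum(w)
    bnd <- vapply(seq_len(n_full) * target, function(b) {
      i <- which(cumw >= b)[1L]
      IRanges::start(mappable)[i] + (b - (cumw[i] - w[i])) - 1L
    }, 0L)
    starts <- c(1L, head(bnd, -1L) + 1L)
    ends <- bnd
    mbp <- rep(target, n_full)
    if (total %% target > 0L) {
      starts <- c(starts, bnd[n_full] + 1L)
      ends <- c(ends, L)
      mbp <- c(mbp, total %% target)
    } else {
      ends[n_full] <- L  # absorb trailing masked tail into the last bin
    }
    out[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                            end = as.integer(ends), mappable_bp = mbp,
                            undersized = FALSE, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Count qualifying read pairs per bin
#'
#' Only concordant pairs with alternative mapping quality at or above
#' `min_alt_quality` (default 35) are counted; each qualifying pair is
#' assigned to the bin containing its fragment midpoint. The column sum
#' equals the number of qualifying pairs exactly.
#'
#' @param records pair data.table.
#' @param bins bin table from [build_mappable_bins()].
#' @param min_alt_quality alternative-mapping-quality floor.
#' @param concordant_span_max concordance span ceiling (bp).
#' @return the bins with a `pair_count` column.
#' @export
count_pairs_in_bins <- function(records, bins, min_alt_quality = 35L,
                                concordant_span_max = 600L) {
  dt <- data.table::as.data.table(records)
  bins$pair_count <- 0L
  if (nrow(dt)) {
    keep <- classify_pair(dt, concordant_span_max) == "concordant" &
      dt$alt_mapq >= min_alt_quality
    dt <- dt[keep]
  }
  if (nrow(dt) == 0L) return(bins)
  mid <- (dt$pos1 + dt$pos2) %/% 2L
  for (ch in unique(dt$chrom1)) {
    b <- which(bins$chrom == ch)
    if (!length(b)) next
    sel <- dt$chrom1 == ch
    idx <- findInterval(mid[sel], bins$start[b])
    idx[idx < 1L] <- 1L
    tab <- tabulate(idx, nbins = length(b))
    bins$pair_count[b] <- bins$pair_count[b] + tab
  }
  bins
}

#' Segment binned read density by circular binary segmentation
#'
#' Recursive CBS: within each chromosome the arc of bins maximizing the
#' standardized mean-difference statistic (computed on square-root
#' transformed counts, a variance-stabilizing choice for Poisson-like
#' data) is accepted as a split when its permutation p-value is below
#' `alpha`, and the resulting pieces are segmented recursively.
#' Deterministic for a given seed. A constant signal yields one segment.
#'
#' @param bin_counts bin table with `chrom`, `start`, `end`, `pair_count`.
#' @param alpha split acceptance threshold on the permutation p-value.
#' @param n_permutations permutations per split test.
#' @param seed RNG seed for the permutations.
#' @param min_width minimum segment width in bins.
#' @param transform variance-stabilizing transform applied before the
#'   statistic (default `sqrt`; use `identity` to disable).
#' @return data.frame of segments: `chrom`, `start_bin`, `end_bin`,
#'   `start`, `end` (bp), `n_bins`, `mean_density` (pairs per bin, original
#'   scale).
#' @export
segment_copy_number <- function(bin_counts, alpha = 0.01,
                                n_permutations = 1000L, seed = 1L,
                                min_width = 3L, transform = sqrt) {
  set.seed(derive_seed(seed, "cbs"))
  out <- list()
  for (ch in unique(bin_counts$chrom)) {
    b <- bin_counts[bin_counts$chrom == ch, , drop = FALSE]
    counts <- b$pair_count
    if (length(counts) < 2L) {
      out[[ch]] <- data.frame(chrom = ch, start_bin = 1L,
                              end_bin = length(counts), start = b$start[1L],
                              end = b$end[length(counts)],
                              n_bins = length(counts),
                              mean_density = mean(counts),
                              stringsAsFactors = FALSE)
      next
    }
    x <- transform(counts)
    boundaries <- cbs_recurse(x, 1L, length(x), alpha, n_permutations,
                              min_width)
    cut <- sort(unique(boundaries))
    seg_start <- c(1L, cut + 1L)
    seg_end <- c(cut, length(x))
    out[[ch]] <- data.frame(
      chrom = ch, start_bin = seg_start, end_bin = seg_end,
      start = b$start[seg_start], end = b$end[seg_end],
      n_bins = seg_end - seg_start + 1L,
      mean_density = vapply(seq_along(seg_start), function(k)
        mean(counts[seg_start[k]:seg_end[k]]), 0.0),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# returns global 1-based boundaries: b means a change between bin b and b+1
cbs_recurse <- function(x, lo, hi, alpha, nperm, minw) {
  n <- hi - lo + 1L
  if (n < 2L * minw) return(integer())
  res <- cbs_best_split(x[lo:hi], minw, nperm, alpha)
  if (res$i < 0L || res$p >= alpha) return(integer())
  cp <- integer()
  if (res$i > 0L) cp <- c(cp, lo - 1L + res$i)
  if (res$j < n) cp <- c(cp, lo - 1L + res$j)
  if (!length(cp)) return(integer())
  pieces <- cbind(c(lo, cp + 1L), c(cp, hi))
  sub <- unlist(lapply(seq_len(nrow(pieces)), function(k)
    cbs_recurse(x, pieces[k, 1L], pieces[k, 2L], alpha, nperm, minw)))
  c(cp, sub)
}
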