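rtriangular <- function(n, lo, mode, hi) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Simulate mapped read pairs for tumor and matched normal
#'
#' Fragments are drawn uniformly from the tumor genome (both haplotypes,
#' 50/50) and from the normal genome, with triangular fragment sizes on
#' `[fragment_size_min, fragment_size_max]`. Each 37-bp end read is mapped
#' back to reference coordinates through the haplotype block map, so pairs
#' straddling an implanted junction acquire exactly the discordant geometry
#' the event implies; reads that cross a junction within the read itself are
#' dropped with a logged count (a real aligner would fail or clip them).
#' PCR duplicates (both ends within 0-1 bp of an existing pair, lower
#' mapping quality), short inverted-pair library artifacts and mismapped
#' pairs are injected at the configured rates on top of `n_pairs` genuine
#' fragments. Positions follow the 5'-end convention: the outermost base of
#' each read.
#'
#' @param dataset implanted `synthetic_dataset`.
#' @param config a [sim_config()]; defaults to the dataset's own.
#' @return the dataset with `tumor_pairs` and `normal_pairs` data.tables and
#'   a `read_log` list (per-category counts and physical coverage).
#' @export
simulate_read_pairs <- function(dataset, config = dataset$config) {
  stopifnot(!is.null(dataset$tumor_genome))
  set.seed(derive_seed(config$seed, "reads"))
  tumor <- sim_sample_pairs(dataset, config, sample_name = "tumor")
  normal <- sim_sample_pairs(dataset, config, sample_name = "normal")
  glen <- sum(nchar(dataset$reference))
  mean_frag <- (config$fragment_size_min + config$fragment_size_mode +
                  config$fragment_size_max) / 3
  coverage <- config$n_pairs * mean_frag / glen
  dataset$tumor_pairs <- tumor$pairs
  dataset$normal_pairs <- normal$pairs
  dataset$read_log <- list(
    physical_coverage = coverage,
    tumor = tumor$log, normal = normal$log)
  msg("physical coverage: %.2fx (%d pairs, %.0f-bp mean fragment, %d-bp genome)",
      coverage, config$n_pairs, mean_frag, glen)
  dataset
}

sim_sample_pairs <- function(dataset, config, sample_name) {
  rl <- config$read_length
  haps <- if (sample_name == "tumor")
    list(dataset$tumor_genome$hapA, dataset$tumor_genome$hapB)
  else list(dataset$normal_genome)
  n <- config$n_pairs
  hap_of <- sample.int(length(haps), n, replace = TRUE)
  frag <- pmax(rl * 2L, as.integer(round(rtriangular(
    n, config$fragment_size_min, config$fragment_size_mode,
    config$fragment_size_max))))
  rows <- vector("list", length(haps))
  dropped <- 0L
  for (h in seq_along(haps)) {
    idx <- which(hap_of == h)
    if (!length(idx)) next
    hp <- haps[[h]]
    lens <- nchar(hp$seq)
    chrom_i <- sample.int(length(lens), length(idx), replace = TRUE,
                          prob = lens / sum(lens))
    fr <- frag[idx]
    start <- floor(runif(length(idx)) * pmax(1, lens[chrom_i] - fr)) + 1L
    tch <- names(lens)[chrom_i]
    # end-read intervals on the haplotype
    m1 <- map_reads(hp$blocks, tch, start, start + rl - 1L, "+")
    m2 <- map_reads(hp$blocks, tch, start + fr - rl, start + fr - 1L, "-")
    ok <- !is.na(m1$pos) & !is.na(m2$pos)
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    rows[[h]] <- data.table::data.table(
      chrom1 = m1$chrom[ok], pos1 = m1$pos[ok], strand1 = m1$strand[ok],
      chrom2 = m2$chrom[ok], pos2 = m2$pos[ok], strand2 = m2$strand[ok])
  }
  pr <- data.table::rbindlist(rows)
  n_gen <- nrow(pr)
  pr[, `:=`(mapq1 = 60L, mapq2 = 60L, alt_mapq = 60L, category = "genuine")]

  # repeat-mask placements get a sub-threshold alternative mapping quality
  in_rep <- near_mask(pr$chrom1, pr$pos1, dataset$masks$repeats) |
    near_mask(pr$chrom2, pr$pos2, dataset$masks$repeats)
  if (any(in_rep))
    pr[in_rep, alt_mapq := sample(0:34, sum(in_rep), replace = TRUE)]

  # mismapped pairs: random coordinates, low alternative quality
  n_mis <- rbinom(1L, n_gen, config$mismap_rate)
  if (n_mis > 0L) {
    mi <- sample.int(n_gen, n_mis)
    rlen <- nchar(dataset$reference)
    mch <- sample(names(rlen), n_mis, replace = TRUE)
    pr[mi, `:=`(chrom2 = mch,
                pos2 = floor(runif(n_mis) * (rlen[mch] - 1000)) + 500L,
                alt_mapq = sample(0:34, n_mis, replace = TRUE),
                category = "mismap")]
  }

  # PCR duplicates: copy existing pairs with 0-1 bp jitter, lower quality
  n_dup <- rbinom(1L, n_gen, config$duplicate_rate)
  dup <- NULL
  if (n_dup > 0L) {
    src <- pr[sample.int(n_gen, n_dup, replace = TRUE)]
    dup <- data.table::copy(src)
    dup[, `:=`(pos1 = pos1 + sample(-1:1, n_dup, replace = TRUE),
               pos2 = pos2 + sample(-1:1, n_dup, replace = TRUE),
               mapq1 = pmax(1L, mapq1 - sample(5:30, n_dup, replace = TRUE)),
               mapq2 = pmax(1L, mapq2 - sample(5:30, n_dup, replace = TRUE)),
               category = "duplicate")]
  }

  # short inverted-pair artifacts: wrong orientation, span < 500 bp
  n_art <- rbinom(1L, n_gen, config$artifact_inverted_pair_rate)
  art <- NULL
  if (n_art > 0L) {
    rlen <- nchar(dataset$reference)
    ach <- sample(names(rlen), n_art, replace = TRUE)
    ap <- floor(runif(n_art) * (rlen[ach] - 2000)) + 1000L
    span <- sample(50:450, n_art, replace = TRUE)
    st <- sample(list(c("-", "+"), c("+", "+"), c("-", "-")), n_art,
                 replace = TRUE)
    art <- data.table::data.table(
      chrom1 = ach, pos1 = as.integer(ap), strand1 = vapply(st, `[`, "", 1L),
      chrom2 = ach, pos2 = as.integer(ap + span),
      strand2 = vapply(st, `[`, "", 2L),
      mapq1 = 60L, mapq2 = 60L, alt_mapq = 60L, category = "artifact")
  }

  pairs <- data.table::rbindlist(list(pr, dup, art), use.names = TRUE)
  pairs[, read_name := sprintf("%s_%07d", sample_name, seq_len(.N))]
  pairs[, sample := sample_name]
  canonicalize_pairs(pairs)
  list(pairs = pairs[],
       log = list(n_genuine = n_gen, n_duplicates = n_dup,
                  n_artifacts = n_art, n_mismapped = n_mis,
                  n_dropped_junction_reads = dropped))
}

# map read intervals [s, e] on haplotype chromosome tch to reference
# 5'-end coordinates; NA when the read crosses a block boundary
map_reads <- function(blocks, tch, s, e, read_strand) {
  n <- length(s)
  out_chrom <- rep(NA_character_, n)
  out_pos <- rep(NA_integer_, n)
  out_strand <- rep(NA_character_, n)
  bl <- data.table::as.data.table(blocks)
  for (ch in unique(tch)) {
    sel <- which(tch == ch)
    b <- bl[tchrom == ch][order(tstart)]
    if (!nrow(b)) next
    i <- findInterval(s[sel], b$tstart)
    valid <- i >= 1L & i <= nrow(b)
    i[!valid] <- 1L
    inside <- valid & s[sel] >= b$tstart[i] & e[sel] <= b$tend[i]
    if (!any(inside)) next
    ii <- i[inside]; ss <- s[sel][inside]; ee <- e[sel][inside]
    t5 <- if (read_strand == "+") ss else ee
    plus_block <- b$strand[ii] == "+"
    pos <- ifelse(plus_block,
                  b$rstart[ii] + (t5 - b$tstart[ii]),
                  b$rend[ii] - (t5 - b$tstart[ii]))
    strand <- ifelse(plus_block, read_strand,
                     ifelse(read_strand == "+", "-", "+"))
    out_chrom[sel[inside]] <- b$ref_chrom[ii]
    out_pos[sel[inside]] <- as.integer(pos)
    out_strand[sel[inside]] <- strand
  }
  list(chrom = out_chrom, pos = out_pos, strand = out_strand)
}

# order ends so end1 <= end2 by (chrom, pos); keeps strand/quality with end
canonicalize_pairs <- function(pairs) {
  flip <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(flip)) {
    tmp <- pairs[flip, list(chrom1, pos1, strand1, mapq1)]
    pairs[flip, `:=`(chrom1 = chrom2, pos1 = pos2, strand1 = strand2,
                     mapq1 = mapq2)]
    pairs[flip, `:=`(chrom2 = tmp$chrom1, pos2 = tmp$pos1,
                     strand2 = tmp$strand1, mapq2 = tmp$mapq1)]
  }
  invisible(pairs)
}
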