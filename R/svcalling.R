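#' Cluster discordant read pairs into candidate rearrangements
#'
#' Two pairs co-cluster iff they share the chromosome pair and strand
#' pattern and both corresponding ends lie within `window` bp (consecutive
#' linkage along the position-sorted pairs). `n_independent` counts members
#' with distinct (pos1, pos2) tuples — duplicate-like pairs support a
#' junction only once.
#'
#' @param records discordant pair data.table (canonical end order).
#' @param window co-clustering window in bp. The default 1 kb is roughly
#'   the library insert ceiling plus three times the insert spread.
#' @return list: `members` (records + `cluster_id`), `clusters` (one row per
#'   cluster: geometry, consensus breakends, support and quality summaries).
#' @export
cluster_discordant_pairs <- function(records, window = 1000L) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    empty <- data.table::data.table(cluster_id = integer(), chrom1 = character(),
      chrom2 = character(), strand1 = character(), strand2 = character(),
      be1 = integer(), be2 = integer(), span = integer(), n_pairs = integer(),
      n_independent = integer(), max_alt_quality = integer(),
      read_name = character())
    return(list(members = dt, clusters = empty))
  }
  dt <- dt[order(chrom1, chrom2, strand1, strand2, pos1, pos2)]
  dt[, cluster_id := {
    newc <- c(TRUE, diff(pos1) > window | abs(diff(pos2)) > window)
    cumsum(newc)
  }, by = list(chrom1, chrom2, strand1, strand2)]
  dt[, cluster_id := .GRP, by = list(chrom1, chrom2, strand1, strand2, cluster_id)]
  clusters <- dt[, list(
    chrom1 = chrom1[1L], chrom2 = chrom2[1L],
    strand1 = strand1[1L], strand2 = strand2[1L],
    be1 = if (strand1[1L] == "+") max(pos1) else min(pos1),
    be2 = if (strand2[1L] == "+") max(pos2) else min(pos2),
    n_pairs = .N,
    n_independent = data.table::uniqueN(paste(pos1, pos2)),
    max_alt_quality = max(alt_mapq),
    read_name = read_name[1L]
  ), by = cluster_id]
  clusters[, span := ifelse(chrom1 == chrom2, abs(be2 - be1), NA_integer_)]
  list(members = dt[], clusters = clusters[])
}

#' Classify a rearrangement call from its breakend geometry
#'
#' With ends in canonical order (end1 leftmost): inward-facing `+/-` pairs
#' separated beyond the insert size arise from deletions; everted `-/+`
#' pairs from tandem duplications; equal strands from inversions; different
#' chromosomes are interchromosomal.
#'
#' @param chrom1,chrom2,strand1,strand2 breakend geometry vectors.
#' @return character vector of event types.
#' @export
classify_event <- function(chrom1, chrom2, strand1, strand2) {
  ifelse(chrom1 != chrom2, "interchromosomal",
    ifelse(strand1 == "+" & strand2 == "-", "deletion",
      ifelse(strand1 == "-" & strand2 == "+", "tandem_duplication",
             "inversion")))
}

change_points_by_chrom <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return(list())
  sp <- split(segments, segments$chrom)
  lapply(sp, function(s) {
    s <- s[order(s$start), ]
    if (nrow(s) < 2L) return(numeric())
    s$start[-1L]  # boundaries between adjacent segments, in bp
  })
}

near_change_point <- function(chrom, pos, cps, window) {
  vapply(seq_along(chrom), function(i) {
    cp <- cps[[chrom[i]]]
    !is.null(cp) && length(cp) > 0 && any(abs(cp - pos[i]) <= window)
  }, TRUE)
}

#' Evaluate candidate clusters against the calling criteria
#'
#' Each cluster is emitted with the lowest-numbered criterion it satisfies:
#'
#' 1. ends >= 10 kb apart, >= 2 independent pairs, at least one pair with
#'    alternative mapping quality >= 35;
#' 2. ends >= 10 kb apart, exactly 1 pair with alternative quality >= 35,
#'    both ends within 100 kb of a copy-number change point;
#' 3. ends >= 600 bp apart, >= 2 independent pairs (one with alternative
#'    quality >= 35), both ends within 100 kb of a change point;
#' 4. ends 600 bp - 10 kb apart, >= 2 independent pairs — manually curated
#'    in the original analysis, so off unless `config$enable_criterion4`.
#'
#' Interchromosomal clusters have no defined separation and are treated as
#' satisfying the span condition of criteria 1-3.
#'
#' @param clusters cluster table from [cluster_discordant_pairs()].
#' @param segments copy-number segment table (needed for criteria 2-3); an
#'   explicit error if missing while those criteria are enabled.
#' @param config a [pipeline_config()].
#' @param use_cn_criteria set FALSE to skip criteria 2-3 (then `segments`
#'   may be NULL).
#' @return calls data.table (clusters + `criterion` + `event_type`).
#' @export
evaluate_criteria <- function(clusters, segments, config = pipeline_config(),
                              use_cn_criteria = TRUE) {
  cl <- data.table::as.data.table(clusters)
  if (use_cn_criteria && is.null(segments))
    stop("criteria 2-3 need copy-number segments; pass segments or set use_cn_criteria = FALSE")
  if (nrow(cl) == 0L) return(cbind(cl, criterion = integer(), event_type = character()))
  inter <- cl$chrom1 != cl$chrom2
  has_q <- cl$max_alt_quality >= config$min_alt_quality
  long <- inter | (!is.na(cl$span) & cl$span >= config$min_span_criterion1)
  mid <- inter | (!is.na(cl$span) & cl$span >= config$concordant_span_max)
  multi <- cl$n_independent >= config$min_independent_pairs
  near_cp <- rep(FALSE, nrow(cl))
  if (use_cn_criteria) {
    cps <- change_points_by_chrom(segments)
    near_cp <- near_change_point(cl$chrom1, cl$be1, cps, config$change_point_window) &
      near_change_point(cl$chrom2, cl$be2, cps, config$change_point_window)
  }
  crit <- rep(NA_integer_, nrow(cl))
  c4 <- !inter & !is.na(cl$span) &
    cl$span >= config$concordant_span_max & cl$span < config$min_span_criterion1 &
    multi & has_q
  if (config$enable_criterion4) crit[c4] <- 4L
  crit[mid & multi & has_q & near_cp] <- 3L
  crit[long & cl$n_independent == 1L & has_q & near_cp] <- 2L
  crit[long & multi & has_q] <- 1L
  calls <- cl[!is.na(crit)]
  calls[, criterion := crit[!is.na(crit)]]
  calls[, event_type := classify_event(chrom1, chrom2, strand1, strand2)]
  calls[]
}

#' Flag amplification-associated calls
#'
#' A call is amplicon-associated iff either breakend falls inside a
#' copy-number segment whose mean bin density is at least
#' `amplification_threshold` times the genome median bin density (median of
#' segment means weighted by segment length in bins).
#'
#' @param calls calls data.table with breakends `be1`, `be2`.
#' @param segments segment table (`chrom`, `start`, `end`, `mean_density`,
#'   `n_bins`).
#' @param amplification_threshold fold change over the median (>=, so a
#'   segment exactly at threshold is flagged).
#' @return the calls with an `amplicon_associated` logical column.
#' @export
flag_amplicon_association <- function(calls, segments,
                                      amplification_threshold = 5) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) { calls[, amplicon_associated := logical()]; return(calls[]) }
  dens <- rep(segments$mean_density, segments$n_bins)
  # zero-density bins (assembly gaps, homozygous losses) are excluded from
  # the baseline so small toy genomes keep a diploid-level median
  med <- stats::median(dens[dens > 0])
  if (!length(dens) || is.na(med)) {
    calls[, amplicon_associated := FALSE]
    return(calls[])
  }
  amp <- segments[segments$mean_density >= amplification_threshold * med, , drop = FALSE]
  hit <- near_mask(calls$chrom1, calls$be1, amp) |
    near_mask(calls$chrom2, calls$be2, amp)
  calls[, amplicon_associated := hit]
  calls[]
}

#' Call somatic rearrangements from filtered discordant pairs
#'
#' Clusters the tumor discordant pairs, evaluates the calling criteria,
#' classifies event types, and (optionally) subtracts candidates supported
#' by at least one pair in the matched normal — the in-silico replacement
#' for the tumor-vs-spleen PCR that established somatic origin in the
#' original protocol.
#'
#' @param discordant filtered tumor discordant pairs.
#' @param segments copy-number segments (criteria 2-3 and amplicon flag).
#' @param config a [pipeline_config()].
#' @param normal_discordant filtered discordant pairs of the matched normal,
#'   or NULL to skip subtraction.
#' @param sample sample label carried into the output.
#' @return calls data.table, one row per somatic rearrangement call.
#' @export
call_rearrangements <- function(discordant, segments,
                                config = pipeline_config(),
                                normal_discordant = NULL,
                                sample = "tumor") {
  cl <- cluster_discordant_pairs(discordant, window = config$cluster_window)
  calls <- evaluate_criteria(cl$clusters, segments, config)
  if (!is.null(segments) && nrow(calls))
    calls <- flag_amplicon_association(calls, segments,
                                       config$amplification_threshold)
  if (config$subtract_normal && !is.null(normal_discordant) && nrow(calls)) {
    germ <- normal_support(calls, normal_discordant, config$cluster_window)
    calls <- calls[!germ]
  }
  if (nrow(calls)) calls[, sample := sample]
  calls[]
}

# TRUE per call when >= 1 normal pair shares geometry within the window
normal_support <- function(calls, normal_discordant, window) {
  nd <- data.table::as.data.table(normal_discordant)
  vapply(seq_len(nrow(calls)), function(i) {
    cc <- calls[i]
    any(nd$chrom1 == cc$chrom1 & nd$chrom2 == cc$chrom2 &
          nd$strand1 == cc$strand1 & nd$strand2 == cc$strand2 &
          abs(nd$pos1 - cc$be1) <= window & abs(nd$pos2 - cc$be2) <= window)
  }, TRUE)
}
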