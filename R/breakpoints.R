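#' Score a base-pair-resolved junction for microhomology / non-templated DNA
#'
#' The junction sequence is anchored to the side-a flank from the left and
#' to the side-b flank from the right. Both flanks are `2w` windows in
#' junction orientation: position `w` of `flank_a` is the last base entering
#' the junction and position `w + 1` of `flank_b` the first base leaving it.
#' Let `L` be the longest common prefix of junction and `flank_a`, and `R`
#' the longest common suffix of junction and `flank_b`, with `J` the
#' junction length. Then
#'
#' * `L + R > J`: the anchors overlap by `L + R - J` bases identical in both
#'   flanks — microhomology of that length;
#' * `L + R == J`: a blunt join (microhomology 0, no insert);
#' * `L + R < J`: the bases between the anchors match neither flank —
#'   a non-templated insert.
#'
#' When several split points give the same maximal anchoring (inherent to
#' microhomology) the leftmost split is the reported breakpoint; the lengths
#' are unaffected. A junction anchored by fewer than `min_anchor` bases on
#' either side is flagged unresolved.
#'
#' @param obs data.frame with columns `event_id`, `junction`, `flank_a`,
#'   `flank_b` (one row per junction), e.g. from [junction_observation()].
#' @param min_anchor minimum anchored bases per side.
#' @return data.frame: `event_id`, `microhomology_length`, `non_templated`,
#'   `resolved`.
#' @export
score_junction <- function(obs, min_anchor = 3L) {
  stopifnot(all(c("event_id", "junction", "flank_a", "flank_b") %in% names(obs)))
  n <- nrow(obs)
  mh <- integer(n); nt <- character(n); resolved <- logical(n)
  for (i in seq_len(n)) {
    J <- nchar(obs$junction[i])
    L <- lcp_len(obs$junction[i], obs$flank_a[i])
    R <- lcs_len(obs$junction[i], obs$flank_b[i])
    if (L < min_anchor || R < min_anchor || J < 2L * min_anchor) {
      mh[i] <- NA_integer_; nt[i] <- NA_character_; resolved[i] <- FALSE
      next
    }
    resolved[i] <- TRUE
    if (L + R >= J) {
      mh[i] <- L + R - J
      nt[i] <- ""
    } else {
      mh[i] <- 0L
      nt[i] <- substr(obs$junction[i], L + 1L, J - R)
    }
  }
  data.frame(event_id = obs$event_id, microhomology_length = mh,
             non_templated = nt, resolved = resolved, stringsAsFactors = FALSE)
}

#' Score every truth junction of a synthetic dataset
#'
#' Convenience wrapper: extracts each implanted junction from the tumor
#' genome and scores it, the round trip used to validate the simulator.
#'
#' @param dataset implanted `synthetic_dataset`.
#' @param width flank half-width (bp).
#' @param min_anchor minimum anchored bases per side.
#' @return signature data.frame with one row per truth event.
#' @export
score_truth_junctions <- function(dataset, width = 10L, min_anchor = 3L) {
  truth <- dataset$truth
  obs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
    junction_observation(dataset, truth[i, ], width = width)))
  score_junction(obs, min_anchor = min_anchor)
}

#' Aggregate junction signatures into a length-binned histogram
#'
#' Produces the per-genotype histogram of microhomology and non-templated
#' sequence lengths, split by amplicon association: counts per (genotype,
#' amplicon flag, class, length bin). Blunt joins count as microhomology of
#' length 0. Lengths at or above the last bin edge are pooled into a
#' terminal "10+"-style bin. Unresolved signatures are excluded and counted
#' in the `n_unresolved` attribute.
#'
#' @param signatures signature data.frame with additional columns `genotype`
#'   and `amplicon_associated`.
#' @param bins integer bin edges for exact lengths; default unit bins 0..10
#'   with a pooled top bin.
#' @return data.frame of counts with the full bin scaffold (zero-filled).
#' @export
aggregate_signatures <- function(signatures, bins = 0:10) {
  stopifnot(all(c("genotype", "amplicon_associated") %in% names(signatures)))
  sig <- signatures[!is.na(signatures$resolved) & signatures$resolved, , drop = FALSE]
  n_unres <- nrow(signatures) - nrow(sig)
  genos <- unique(signatures$genotype)
  if (!length(genos)) genos <- character()
  bin_labels <- c(as.character(bins), paste0(max(bins) + 1L, "+"))
  scaffold <- data.table::CJ(genotype = genos,
                             amplicon_associated = c(FALSE, TRUE),
                             class = c("microhomology", "non_templated"),
                             length_bin = bin_labels, sorted = FALSE)
  if (nrow(sig)) {
    len <- ifelse(nzchar(sig$non_templated) & !is.na(sig$non_templated),
                  nchar(sig$non_templated), sig$microhomology_length)
    cls <- ifelse(nzchar(sig$non_templated) & !is.na(sig$non_templated),
                  "non_templated", "microhomology")
    lab <- ifelse(len > max(bins), paste0(max(bins) + 1L, "+"),
                  as.character(len))
    tab <- data.table::data.table(genotype = sig$genotype,
                                  amplicon_associated = sig$amplicon_associated,
                                  class = cls, length_bin = lab)
    tab <- tab[, list(count = .N),
               by = c("genotype", "amplicon_associated", "class", "length_bin")]
  } else {
    tab <- data.table::data.table(genotype = character(),
                                  amplicon_associated = logical(),
                                  class = character(), length_bin = character(),
                                  count = integer())
  }
  out <- merge(scaffold, tab,
               by = c("genotype", "amplicon_associated", "class", "length_bin"),
               all.x = TRUE, sort = FALSE)
  out$count[is.na(out$count)] <- 0L
  out <- as.data.frame(out)
  attr(out, "n_unresolved") <- n_unres
  out
}

#' Flag shard junctions for exclusion from breakpoint aggregation
#'
#' Small fragments caught up in complex rearrangements ("shards") distort
#' junction statistics. The operational stand-in used here: an event is a
#' shard candidate when any of its breakends lies within `dist` bp of
#' another event's breakend in the same sample.
#'
#' @param events data.frame with `sample`, `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param dist proximity threshold in bp.
#' @return logical vector, TRUE for shard candidates.
#' @export
flag_shards <- function(events, dist = 2000L) {
  n <- nrow(events)
  out <- logical(n)
  if (n < 2L) return(out)
  be <- rbind(
    data.frame(i = seq_len(n), sample = events$sample,
               chrom = events$chrom1, pos = events$pos1),
    data.frame(i = seq_len(n), sample = events$sample,
               chrom = events$chrom2, pos = events$pos2))
  for (i in seq_len(n)) {
    mine <- be[be$i == i, ]
    other <- be[be$i != i & be$sample == events$sample[i], ]
    for (k in seq_len(nrow(mine))) {
      hit <- other$chrom == mine$chrom[k] &
        abs(other$pos - mine$pos[k]) <= dist
      if (any(hit)) { out[i] <- TRUE; break }
    }
  }
  out
}
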