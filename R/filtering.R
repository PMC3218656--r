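pair_span <- function(records) {
  ifelse(records$chrom1 == records$chrom2,
         abs(records$pos2 - records$pos1), NA_integer_)
}

#' Classify read pairs as concordant or discordant
#'
#' A pair is concordant iff both ends map to the same chromosome, in the
#' inward-facing orientation expected of an intact library fragment (`+` end
#' leftmost, `-` end rightmost), no further apart than `expected_span_max`.
#' Anything else — wrong orientation, excessive separation, or different
#' chromosomes — is discordant and potentially marks a rearrangement.
#'
#' @param records pair data.frame/data.table (canonical end order: end1 is
#'   the lesser (chrom, pos)).
#' @param expected_span_max maximum concordant span in bp. The default 600
#'   sits just above the 550-bp library insert ceiling and matches the
#'   boundary the calling criteria use for "reads mapping >= 600 bp apart".
#' @return character vector: "concordant" or "discordant".
#' @export
classify_pair <- function(records, expected_span_max = 600L) {
  span <- pair_span(records)
  conc <- records$chrom1 == records$chrom2 &
    records$strand1 == "+" & records$strand2 == "-" &
    !is.na(span) & span <= expected_span_max
  ifelse(conc, "concordant", "discordant")
}

#' Remove PCR duplicates
#'
#' Pairs where both ends map to identical locations plus or minus a single
#' nucleotide (same chromosomes and strands) are grouped as PCR duplicates
#' of one library fragment; only the pair with the highest total mapping
#' quality is retained per group (ties broken by the lexicographically
#' smallest read name, for determinism). Because the +/-1-bp relation is
#' not transitive, groups are the connected components of that relation
#' (union-find over position-sorted records).
#'
#' @param records pair data.table.
#' @param window bp tolerance (1 reproduces the published rule).
#' @return list: `records` (retained), `removed` (dropped duplicates),
#'   `removed_count`.
#' @export
remove_pcr_duplicates <- function(records, window = 1L) {
  dt <- data.table::as.data.table(records)
  n <- nrow(dt)
  if (n == 0L)
    return(list(records = dt, removed = dt[0], removed_count = 0L))
  dt[, .dup_i := .I]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  grp <- dt[, list(idx = list(.dup_i[order(pos1, pos2)])),
            by = list(chrom1, strand1, chrom2, strand2)]
  for (g in grp$idx) {
    if (length(g) < 2L) next
    p1 <- dt$pos1[g]; p2 <- dt$pos2[g]
    lo <- 1L
    for (k in 2L:length(g)) {
      while (p1[k] - p1[lo] > window) lo <- lo + 1L
      if (lo > k - 1L) next
      for (j in lo:(k - 1L)) {
        if (abs(p2[k] - p2[j]) <= window) {
          rk <- find(g[k]); rj <- find(g[j])
          if (rk != rj) parent[rk] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  qual <- dt$mapq1 + dt$mapq2
  dt[, `:=`(.root = root, .qual = qual)]
  keep <- dt[order(-.qual, read_name), .SD[1L], by = .root]$.dup_i
  removed <- dt[!.dup_i %in% keep]
  retained <- dt[.dup_i %in% keep]
  retained[, c(".dup_i", ".root", ".qual") := NULL]
  removed[, c(".dup_i", ".root", ".qual") := NULL]
  list(records = retained[], removed = removed[],
       removed_count = nrow(removed))
}

#' Apply repeat, assembly-gap and germline-SV region filters
#'
#' A pair is removed with reason `repeat_overlap` when either end lies in
#' the repeat mask; `gap_proximity` when either end lies within
#' `gap_exclusion` (default 1 Mb) of an assembly-gap interval; and
#' `germline_sv_proximity` when *both* ends lie within `germline_proximity`
#' (default 500 bp) of a germline structural variant breakend. The first
#' matching reason in that order is reported. Mask intervals on chromosomes
#' absent from the records are ignored with a warning.
#'
#' @param records pair data.table.
#' @param repeat_mask,gap_mask data.frames (chrom, start, end).
#' @param germline_svs data.frame (chrom, start, end); start and end are the
#'   SV breakends.
#' @param gap_exclusion,germline_proximity distances in bp.
#' @return list: `records` (retained), `removed` (with `removal_reason`).
#' @export
apply_region_filters <- function(records, repeat_mask = NULL, gap_mask = NULL,
                                 germline_svs = NULL,
                                 gap_exclusion = 1000000L,
                                 germline_proximity = 500L) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt)) {
    known <- unique(c(dt$chrom1, dt$chrom2))
    for (m in list(repeat_mask, gap_mask, germline_svs)) {
      if (!is.null(m) && nrow(m) && !all(m$chrom %in% known)) {
        warning(sprintf("mask intervals on unknown chromosome(s) ignored: %s",
                        paste(setdiff(unique(m$chrom), known), collapse = ",")))
      }
    }
  }
  reason <- rep(NA_character_, nrow(dt))
  rep_hit <- near_mask(dt$chrom1, dt$pos1, repeat_mask) |
    near_mask(dt$chrom2, dt$pos2, repeat_mask)
  gap_hit <- near_mask(dt$chrom1, dt$pos1, gap_mask, slop = gap_exclusion) |
    near_mask(dt$chrom2, dt$pos2, gap_mask, slop = gap_exclusion)
  germ_be <- germline_breakends(germline_svs)
  germ_hit <- near_mask(dt$chrom1, dt$pos1, germ_be, slop = germline_proximity) &
    near_mask(dt$chrom2, dt$pos2, germ_be, slop = germline_proximity)
  reason[germ_hit] <- "germline_sv_proximity"
  reason[gap_hit] <- "gap_proximity"
  reason[rep_hit] <- "repeat_overlap"
  list(records = dt[is.na(reason)],
       removed = cbind(dt[!is.na(reason)],
                       removal_reason = reason[!is.na(reason)]))
}

germline_breakends <- function(germline_svs) {
  if (is.null(germline_svs) || nrow(germline_svs) == 0L) return(NULL)
  data.frame(chrom = rep(germline_svs$chrom, 2L),
             start = c(germline_svs$start, germline_svs$end),
             end = c(germline_svs$start, germline_svs$end),
             stringsAsFactors = FALSE)
}

#' Remove short wrong-orientation singleton artifacts
#'
#' Library artifacts (intramolecular rearrangement during amplification,
#' mispriming in the cluster) produce pairs whose ends map within less than
#' `artifact_span` bp of one another in the incorrect orientation. Such a
#' pair is removed unless a second independent pair supports the same
#' putative junction, i.e. co-clusters with it under the calling module's
#' clustering rule.
#'
#' @param records discordant pair data.table.
#' @param artifact_span span threshold in bp (exclusive; default 500).
#' @param cluster_window clustering window in bp.
#' @return list: `records` (retained), `removed`.
#' @export
remove_inverted_singletons <- function(records, artifact_span = 500L,
                                       cluster_window = 1000L) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) return(list(records = dt, removed = dt[0]))
  span <- pair_span(dt)
  wrong <- dt$chrom1 == dt$chrom2 &
    !(dt$strand1 == "+" & dt$strand2 == "-") &
    !is.na(span) & span < artifact_span
  cl <- cluster_discordant_pairs(dt, window = cluster_window)
  support <- cl$members[, list(n_independent = data.table::uniqueN(paste(pos1, pos2))),
                        by = cluster_id]
  mem <- merge(cl$members[, list(read_name, cluster_id)], support,
               by = "cluster_id")
  dt <- merge(dt, mem[, list(read_name, n_independent)], by = "read_name",
              all.x = TRUE, sort = FALSE)
  drop <- wrong & (is.na(dt$n_independent) | dt$n_independent < 2L)
  removed <- dt[drop]
  retained <- dt[!drop]
  retained[, n_independent := NULL]
  removed[, n_independent := NULL]
  list(records = retained[], removed = removed[])
}

#' Run the full read-pair exclusion cascade
#'
#' Applies, in order: the low-confidence-mapping floor (off by default),
#' PCR-duplicate removal, the repeat/gap/germline region filters,
#' concordant/discordant classification, and short-inverted-singleton
#' artifact removal among the discordant pairs. Every input record receives
#' exactly one status; removal counts per reason are returned alongside.
#'
#' @param records pair data.table.
#' @param masks list with `repeats`, `gaps`, `germline_sv` data.frames (as
#'   in a `synthetic_dataset`).
#' @param config a [pipeline_config()].
#' @return list: `outcomes` (all records with `status` and
#'   `removal_reason`), `discordant` (retained discordant pairs),
#'   `concordant` (retained concordant pairs), `counts` (named removals).
#' @export
filter_pairs <- function(records, masks, config = pipeline_config()) {
  dt <- data.table::as.data.table(records)
  out <- list()
  mark <- function(x, status, reason = NA_character_) {
    if (nrow(x) == 0L) return(NULL)
    x <- data.table::copy(x)
    if (!"removal_reason" %in% names(x)) x[, removal_reason := reason]
    x[, status := status]
    x
  }

  lowq <- dt[alt_mapq < config$min_low_confidence]
  out$lowq <- mark(lowq, "removed", "low_confidence_mapping")
  dt <- dt[alt_mapq >= config$min_low_confidence]

  dup <- remove_pcr_duplicates(dt, window = config$duplicate_window)
  out$dup <- mark(dup$removed, "removed", "pcr_duplicate")
  dt <- dup$records

  reg <- apply_region_filters(dt, masks$repeats, masks$gaps,
                              masks$germline_sv,
                              gap_exclusion = config$gap_exclusion,
                              germline_proximity = config$germline_proximity)
  out$region <- mark(reg$removed, "removed")
  dt <- reg$records

  cls <- classify_pair(dt, expected_span_max = config$concordant_span_max)
  conc <- dt[cls == "concordant"]
  disc <- dt[cls == "discordant"]
  out$conc <- mark(conc, "retained_concordant")

  inv <- remove_inverted_singletons(disc,
                                    artifact_span = config$inverted_artifact_span,
                                    cluster_window = config$cluster_window)
  out$inv <- mark(inv$removed, "removed", "inverted_singleton_artifact")
  out$disc <- mark(inv$records, "retained_discordant")

  outcomes <- data.table::rbindlist(out, use.names = TRUE, fill = TRUE)
  counts <- table(outcomes$removal_reason[outcomes$status == "removed"])
  list(outcomes = outcomes[],
       discordant = inv$records,
       concordant = conc,
       counts = as.list(counts))
}
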