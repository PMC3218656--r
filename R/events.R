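#' Construct a truth rearrangement event
#'
#' The interval `[start, end]` is interpreted per event type: the deleted
#' segment (deletion), the duplicated segment (tandem duplication /
#' amplification), or the inverted segment (inversion). For interchromosomal
#' events `start` is the breakend on `chrom` and `end` the breakend on
#' `chrom2`; a balanced pair of derivative chromosomes is produced.
#' Breakend strands follow the discordant read-pair convention: a `+`
#' breakend retains sequence to its left, a `-` breakend retains sequence to
#' its right.
#'
#' A junction may carry either `microhomology` (> 0 bp of identical sequence
#' on both flanks) or a `non_templated` insert, never both.
#'
#' @param event_type one of deletion, tandem_duplication, inversion,
#'   amplification, interchromosomal.
#' @param chrom,start,end chromosome and interval (see above).
#' @param chrom2 second chromosome (interchromosomal only).
#' @param microhomology requested microhomology length at the junction (bp).
#' @param non_templated requested non-templated insert (DNA string).
#' @param somatic logical; germline events are also present in the normal.
#' @param homozygous logical; homozygous events hit both tumor haplotypes.
#' @param copies number of copies for amplification (>= 2).
#' @return one-row data.frame (truth event record).
#' @export
truth_event <- function(event_type, chrom, start, end, chrom2 = NULL,
                        microhomology = 0L, non_templated = "",
                        somatic = TRUE, homozygous = FALSE, copies = 2L) {
  event_type <- match.arg(event_type,
    c("deletion", "tandem_duplication", "inversion", "amplification",
      "interchromosomal"))
  if (microhomology > 0L && nzchar(non_templated))
    stop("microhomology and non_templated insert are mutually exclusive")
  start <- as.integer(start); end <- as.integer(end)
  if (event_type == "interchromosomal") {
    if (is.null(chrom2)) stop("interchromosomal events need chrom2")
    be <- list(chrom1 = chrom, pos1 = start, strand1 = "+",
               chrom2 = chrom2, pos2 = end, strand2 = "-", span = NA_integer_)
  } else {
    if (start >= end) stop("start must be < end")
    be <- switch(event_type,
      deletion = list(chrom1 = chrom, pos1 = start - 1L, strand1 = "+",
                      chrom2 = chrom, pos2 = end + 1L, strand2 = "-",
                      span = end - start + 1L),
      tandem_duplication = ,
      amplification = list(chrom1 = chrom, pos1 = start, strand1 = "-",
                           chrom2 = chrom, pos2 = end, strand2 = "+",
                           span = end - start + 1L),
      inversion = list(chrom1 = chrom, pos1 = start, strand1 = "+",
                       chrom2 = chrom, pos2 = end, strand2 = "+",
                       span = end - start + 1L))
  }
  data.frame(event_id = NA_character_, event_type = event_type,
             chrom1 = be$chrom1, pos1 = be$pos1, strand1 = be$strand1,
             chrom2 = be$chrom2, pos2 = be$pos2, strand2 = be$strand2,
             start = start, end = end, span = be$span,
             microhomology_length = as.integer(microhomology),
             non_templated = non_templated,
             somatic = isTRUE(somatic), homozygous = isTRUE(homozygous),
             copies = as.integer(copies), stringsAsFactors = FALSE)
}

empty_truth <- function() truth_event("deletion", "chr1", 1, 2)[0, ]

#' Implant rearrangement events into a synthetic dataset
#'
#' Edits the reference so every requested junction carries exactly the
#' requested microhomology or non-templated insert, then builds the tumor
#' genome (two haplotypes: haplotype A carries all events, haplotype B the
#' germline and homozygous somatic events) and the matched-normal genome
#' (germline events only). Truth rows already present in the dataset
#' (germline deletions from [simulate_genome()]) are implanted alongside the
#' events supplied here. Realized junction values are verified against the
#' request; inversion junctions, where the right flank enters the junction in
#' reverse orientation, record their realized values.
#'
#' @param dataset a `synthetic_dataset` from [simulate_genome()].
#' @param events data.frame of [truth_event()] rows (somatic events to add).
#' @return the dataset with `tumor_genome`, `normal_genome` and an updated
#'   `truth` table (including per-event junction coordinates).
#' @export
implant_events <- function(dataset, events = empty_truth()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  all_events <- rbind(dataset$truth[, names(empty_truth())], events)
  if (nrow(all_events)) {
    all_events$event_id <- sprintf("ev%03d", seq_len(nrow(all_events)))
    check_event_compatibility(all_events)
  }

  ref <- dataset$reference
  # 1. junction sequence forcing (reference edits), skipped for inversions;
  #    requested non-templated inserts are adjusted so they cannot extend a
  #    flank match, and the truth table records the realized insert
  for (i in seq_len(nrow(all_events))) {
    ev <- all_events[i, ]
    if (ev$event_type == "inversion") next
    js <- junction_sides(ev)
    ref <- force_junction(ref, js$L, js$R, ev$microhomology_length,
                          ev$non_templated)
    if (nzchar(ev$non_templated))
      all_events$non_templated[i] <- sanitize_insert(ref, js$L, js$R,
                                                     ev$non_templated)
  }
  dataset$reference <- ref

  germline <- all_events[!all_events$somatic, , drop = FALSE]
  homo <- all_events[!all_events$somatic | all_events$homozygous, , drop = FALSE]

  hapA <- build_haplotype(ref, all_events)
  hapB <- build_haplotype(ref, homo)
  normal <- build_haplotype(ref, germline)

  dataset$tumor_genome <- list(hapA = hapA, hapB = hapB)
  dataset$normal_genome <- normal

  # 2. realized junction check / fill-in
  if (nrow(all_events)) {
    for (i in seq_len(nrow(all_events))) {
      ev <- all_events[i, ]
      obs <- junction_observation(dataset, ev, width = 20L)
      sig <- score_junction(obs)
      if (ev$event_type == "inversion") {
        all_events$microhomology_length[i] <- sig$microhomology_length
        all_events$non_templated[i] <- sig$non_templated
      } else if (sig$microhomology_length != ev$microhomology_length ||
                 sig$non_templated != ev$non_templated) {
        stop(sprintf("junction forcing failed for %s (wanted mh=%d nt='%s', got mh=%d nt='%s')",
                     ev$event_id, ev$microhomology_length, ev$non_templated,
                     sig$microhomology_length, sig$non_templated))
      }
    }
  }
  dataset$truth <- all_events
  dataset
}

check_event_compatibility <- function(events) {
  intra <- events[events$event_type != "interchromosomal", , drop = FALSE]
  tra <- events[events$event_type == "interchromosomal", , drop = FALSE]
  if (nrow(intra) > 1L) {
    for (ch in unique(intra$chrom1)) {
      e <- intra[intra$chrom1 == ch, , drop = FALSE]
      if (nrow(e) < 2L) next
      ir <- IRanges::IRanges(e$start, e$end)
      ov <- IRanges::findOverlaps(ir, ir)
      bad <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
      if (length(bad))
        stop(sprintf("overlapping incompatible events: %s and %s",
                     e$event_id[S4Vectors::queryHits(bad)[1]],
                     e$event_id[S4Vectors::subjectHits(bad)[1]]))
    }
  }
  if (nrow(tra)) {
    shared <- intersect(c(tra$chrom1, tra$chrom2), intra$chrom1)
    if (length(shared))
      stop(sprintf("interchromosomal event on %s cannot be combined with intra-chromosomal events on the same chromosome",
                   shared[1]))
    if (anyDuplicated(c(tra$chrom1, tra$chrom2)))
      stop("at most one interchromosomal event per chromosome")
  }
  invisible(events)
}

# Junction sides in entering/leaving orientation:
#  L = (chrom, pos, orient): sequence entering the junction ends at ref pos
#  R = (chrom, pos, orient): sequence leaving the junction starts at ref pos
junction_sides <- function(ev) {
  switch(ev$event_type,
    deletion = list(L = list(ev$chrom1, ev$pos1, "+"),
                    R = list(ev$chrom2, ev$pos2, "+")),
    tandem_duplication = ,
    amplification = list(L = list(ev$chrom1, ev$end, "+"),
                         R = list(ev$chrom1, ev$start, "+")),
    inversion = list(L = list(ev$chrom1, ev$start - 1L, "+"),
                     R = list(ev$chrom1, ev$end, "-")),
    interchromosomal = list(L = list(ev$chrom1, ev$pos1, "+"),
                            R = list(ev$chrom2, ev$pos2, "+")))
}

set_base <- function(ref, chrom, pos, avoid) {
  cur <- substr(ref[[chrom]], pos, pos)
  if (!cur %in% avoid) return(ref)
  repl <- setdiff(BASES, avoid)[1]
  substr(ref[[chrom]], pos, pos) <- repl
  ref
}

get_seq <- function(ref, chrom, s, e) substr(ref[[chrom]], s, e)

# Edit the reference so the junction joining L=(chl,pl,+) to R=(chr,pr,+)
# scores exactly mh=k / nt=ins. With A = ref[..pl] and B = ref[pr..], the
# scored microhomology is i + j where i = suffix of A matching ref[..pr-1]
# and j = prefix of B matching ref[pl+1..]. We force i = k and break any
# further extension on either side.
force_junction <- function(ref, L, R, k, ins) {
  chl <- L[[1]]; pl <- L[[2]]
  chr <- R[[1]]; pr <- R[[2]]
  m <- nchar(ins)
  if (m > 0L) {
    # the insert itself is adjusted by sanitize_insert(); no reference edit
    return(ref)
  }
  if (k > 0L) {
    tmpl <- get_seq(ref, chl, pl - k + 1L, pl)
    substr(ref[[chr]], pr - k, pr - 1L) <- tmpl
  }
  # break extension: i stops at k, j stays 0
  a_prev <- substr(ref[[chl]], pl - k, pl - k)
  ref <- set_base(ref, chr, pr - k - 1L, a_prev)
  a_next <- substr(ref[[chl]], pl + 1L, pl + 1L)
  ref <- set_base(ref, chr, pr, a_next)
  ref
}

# ensure a requested non-templated insert cannot extend either flank match
sanitize_insert <- function(ref, L, R, ins) {
  if (!nzchar(ins)) return(ins)
  chl <- L[[1]]; pl <- L[[2]]; chr <- R[[1]]; pr <- R[[2]]
  a_next <- substr(ref[[chl]], pl + 1L, pl + 1L)
  b_prev <- substr(ref[[chr]], pr - 1L, pr - 1L)
  v <- strsplit(ins, "", fixed = TRUE)[[1]]
  if (v[1] == a_next) v[1] <- setdiff(BASES, c(a_next, b_prev))[1]
  if (v[length(v)] == b_prev)
    v[length(v)] <- setdiff(BASES, c(a_next, b_prev))[1]
  paste(v, collapse = "")
}

# Build one haplotype: returns list(seq = named character vector,
# blocks = data.frame(tchrom, tstart, tend, ref_chrom, rstart, rend, strand),
# junctions = data.frame(event_id, tchrom, tpos, nt_len))
build_haplotype <- function(ref, events) {
  seqs <- list(); blocks <- list(); juncs <- list()
  tra <- events[events$event_type == "interchromosomal", , drop = FALSE]
  tra_chroms <- c(tra$chrom1, tra$chrom2)
  for (ch in names(ref)) {
    if (ch %in% tra_chroms) next
    evs <- events[events$event_type != "interchromosomal" &
                    events$chrom1 == ch, , drop = FALSE]
    evs <- evs[order(evs$start), , drop = FALSE]
    hb <- build_linear_chrom(ref, ch, ch, evs)
    seqs[[ch]] <- unname(hb$seq)
    blocks[[ch]] <- hb$blocks; juncs[[ch]] <- hb$junctions
  }
  for (i in seq_len(nrow(tra))) {
    ev <- tra[i, ]
    L1 <- nchar(ref[[ev$chrom1]]); L2 <- nchar(ref[[ev$chrom2]])
    ins <- sanitize_insert(ref, list(ev$chrom1, ev$pos1), list(ev$chrom2, ev$pos2),
                           ev$non_templated)
    der1 <- paste0(get_seq(ref, ev$chrom1, 1L, ev$pos1), ins,
                   get_seq(ref, ev$chrom2, ev$pos2, L2))
    n1 <- paste0("der_", ev$chrom1)
    seqs[[n1]] <- der1
    blocks[[n1]] <- data.frame(
      tchrom = n1,
      tstart = c(1L, ev$pos1 + nchar(ins) + 1L),
      tend = c(ev$pos1, nchar(der1)),
      ref_chrom = c(ev$chrom1, ev$chrom2),
      rstart = c(1L, ev$pos2), rend = c(ev$pos1, L2),
      strand = "+", stringsAsFactors = FALSE)
    juncs[[n1]] <- data.frame(event_id = ev$event_id, tchrom = n1,
                              tpos = ev$pos1, nt_len = nchar(ins),
                              stringsAsFactors = FALSE)
    # reciprocal derivative keeps the haplotype copy-number neutral
    der2 <- paste0(get_seq(ref, ev$chrom2, 1L, ev$pos2 - 1L),
                   get_seq(ref, ev$chrom1, ev$pos1 + 1L, L1))
    n2 <- paste0("der_", ev$chrom2)
    seqs[[n2]] <- der2
    blocks[[n2]] <- data.frame(
      tchrom = n2, tstart = c(1L, ev$pos2),
      tend = c(ev$pos2 - 1L, nchar(der2)),
      ref_chrom = c(ev$chrom2, ev$chrom1),
      rstart = c(1L, ev$pos1 + 1L), rend = c(ev$pos2 - 1L, L1),
      strand = "+", stringsAsFactors = FALSE)
    juncs[[n2]] <- NULL
  }
  list(seq = unlist(seqs),
       blocks = do.call(rbind, c(unname(blocks), list(make.row.names = FALSE))),
       junctions = {
         j <- do.call(rbind, c(unname(juncs), list(make.row.names = FALSE)))
         if (is.null(j)) data.frame(event_id = character(), tchrom = character(),
                                    tpos = integer(), nt_len = integer(),
                                    stringsAsFactors = FALSE) else j
       })
}

build_linear_chrom <- function(ref, ch, out_name, evs) {
  L <- nchar(ref[[ch]])
  pieces <- character(); pblocks <- list(); pj <- list()
  tcur <- 0L  # bases emitted so far
  cursor <- 1L
  emit <- function(s, e, strand = "+") {
    if (e < s) return(invisible(NULL))
    seqp <- get_seq(ref, ch, s, e)
    if (strand == "-") seqp <- revcomp(seqp)
    pieces[[length(pieces) + 1L]] <<- seqp
    pblocks[[length(pblocks) + 1L]] <<- data.frame(
      tchrom = out_name, tstart = tcur + 1L, tend = tcur + nchar(seqp),
      ref_chrom = ch, rstart = s, rend = e, strand = strand,
      stringsAsFactors = FALSE)
    tcur <<- tcur + nchar(seqp)
  }
  emit_ins <- function(ins) {
    if (!nzchar(ins)) return(invisible(NULL))
    pieces[[length(pieces) + 1L]] <<- ins
    tcur <<- tcur + nchar(ins)  # insert bases intentionally have no block
  }
  for (i in seq_len(nrow(evs))) {
    ev <- evs[i, ]
    emit(cursor, ev$start - 1L)
    if (ev$event_type == "deletion") {
      ins <- sanitize_insert(ref, list(ch, ev$start - 1L), list(ch, ev$end + 1L),
                             ev$non_templated)
      pj[[length(pj) + 1L]] <- data.frame(event_id = ev$event_id,
        tchrom = out_name, tpos = tcur, nt_len = nchar(ins),
        stringsAsFactors = FALSE)
      emit_ins(ins)
    } else if (ev$event_type %in% c("tandem_duplication", "amplification")) {
      ncopy <- if (ev$event_type == "tandem_duplication") 2L else ev$copies
      ins <- sanitize_insert(ref, list(ch, ev$end), list(ch, ev$start),
                             ev$non_templated)
      for (cpy in seq_len(ncopy)) {
        emit(ev$start, ev$end)
        if (cpy < ncopy) {
          if (cpy == 1L)
            pj[[length(pj) + 1L]] <- data.frame(event_id = ev$event_id,
              tchrom = out_name, tpos = tcur, nt_len = nchar(ins),
              stringsAsFactors = FALSE)
          emit_ins(ins)
        }
      }
    } else if (ev$event_type == "inversion") {
      pj[[length(pj) + 1L]] <- data.frame(event_id = ev$event_id,
        tchrom = out_name, tpos = tcur, nt_len = 0L,
        stringsAsFactors = FALSE)
      emit(ev$start, ev$end, strand = "-")
    }
    cursor <- ev$end + 1L
    if (ev$event_type == "deletion") cursor <- ev$end + 1L
  }
  emit(cursor, L)
  list(seq = setNames(paste(unlist(pieces), collapse = ""), out_name),
       blocks = do.call(rbind, c(pblocks, list(make.row.names = FALSE))),
       junctions = if (length(pj))
         do.call(rbind, c(pj, list(make.row.names = FALSE)))
       else data.frame(event_id = character(), tchrom = character(),
                       tpos = integer(), nt_len = integer(),
                       stringsAsFactors = FALSE))
}

#' Extract the junction observation for one truth event
#'
#' Pulls the sequenced-across-the-junction string from tumor haplotype A and
#' the two reference flank windows, in the orientation entering/leaving the
#' junction, ready for [score_junction()].
#'
#' @param dataset implanted `synthetic_dataset`.
#' @param ev one-row truth event.
#' @param width flank half-width in bp (10 or 100 in the standard analysis).
#' @return one-row data.frame (`event_id`, `junction`, `flank_a`, `flank_b`).
#' @export
junction_observation <- function(dataset, ev, width = 10L) {
  hap <- dataset$tumor_genome$hapA
  j <- hap$junctions[hap$junctions$event_id == ev$event_id, , drop = FALSE]
  if (nrow(j) == 0L) stop(sprintf("no junction recorded for %s", ev$event_id))
  j <- j[1L, ]
  tseq <- hap$seq[[j$tchrom]]
  junction <- substr(tseq, j$tpos - width + 1L, j$tpos + j$nt_len + width)
  js <- junction_sides(ev)
  flank_a <- ref_flank(dataset$reference, js$L, width, side = "a")
  flank_b <- ref_flank(dataset$reference, js$R, width, side = "b")
  data.frame(event_id = ev$event_id, junction = junction,
             flank_a = flank_a, flank_b = flank_b, stringsAsFactors = FALSE)
}

# Flank windows of length 2w in junction orientation:
#  side "a": position w is the last base entering the junction
#  side "b": position w+1 is the first base leaving the junction
# For a minus-orientation side the window is the reverse complement of the
# corresponding reference window, so both flanks read 5'->3' across the join.
ref_flank <- function(ref, side_spec, w, side = c("a", "b")) {
  side <- match.arg(side)
  ch <- side_spec[[1]]; pos <- side_spec[[2]]; orient <- side_spec[[3]]
  if (orient == "+") {
    if (side == "a") get_seq(ref, ch, pos - w + 1L, pos + w)
    else get_seq(ref, ch, pos - w, pos + w - 1L)
  } else {
    if (side == "a") revcomp(get_seq(ref, ch, pos - w, pos + w - 1L))
    else revcomp(get_seq(ref, ch, pos - w + 1L, pos + w))
  }
}
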