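# Readers/writers for the standard formats. Internal coordinates are
# 1-based inclusive; BED/BEDPE files are written 0-based half-open, TSV
# mirrors stay 1-based and say so in a header comment.

#' Write chromosome sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a 3-column BED file (0-based half-open)
#' @param df data.frame with chrom/start/end (1-based inclusive).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file into 1-based inclusive intervals
#' @param path BED path.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- df$start + 1L
  df
}

#' Write rearrangements as BEDPE (0-based half-open breakend windows)
#' @param events calls or truth data.frame with `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (or `be1`/`be2` for calls) and optional
#'   `event_id`/`n_pairs`/`event_type`/`criterion`.
#' @param path output path.
#' @export
write_bedpe <- function(events, path) {
  p1 <- events$pos1 %||% events$be1
  p2 <- events$pos2 %||% events$be2
  if (is.null(p1)) { p1 <- events$be1; p2 <- events$be2 }
  out <- data.frame(
    chrom1 = events$chrom1, start1 = p1 - 1L, end1 = p1,
    chrom2 = events$chrom2, start2 = p2 - 1L, end2 = p2,
    name = events$event_id %||% sprintf("call%03d", seq_len(nrow(events))),
    score = events$n_pairs %||% 0L,
    strand1 = events$strand1, strand2 = events$strand2,
    type = events$event_type %||% ".",
    criterion = events$criterion %||% ".")
  con <- file(path, "w")
  writeLines("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\tstrand1\tstrand2\ttype\tcriterion", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write the read-pair table in the TSV pair dialect
#' @param pairs pair data.table.
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  con <- file(path, "w")
  writeLines("# pair table; coordinates are 1-based 5'-end positions", con)
  close(con)
  data.table::fwrite(pairs, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Read the TSV pair dialect
#' @param path pair TSV path.
#' @export
read_pairs_tsv <- function(path) {
  data.table::fread(path, sep = "\t", skip = "read_name")
}

#' Write pairs as a coordinate-sorted SAM file
#'
#' Minimal SAM emission for interoperability: fixed 37M CIGAR, no
#' sequence/quality strings, the pair alternative mapping quality in the
#' `AM:i` tag. Positions are converted from the internal 5'-end convention
#' to leftmost-base POS.
#'
#' @param pairs pair data.table.
#' @param chrom_lengths named integer vector.
#' @param path output path.
#' @param read_length read length used for the CIGAR/leftmost conversion.
#' @export
write_sam <- function(pairs, chrom_lengths, path, read_length = 37L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  dt <- data.table::as.data.table(pairs)
  left <- function(pos, strand) ifelse(strand == "+", pos,
                                       pos - read_length + 1L)
  rec <- function(qname, flag, ch, pos, mapq, mch, mpos, am) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*\tAM:i:%d",
            qname, flag, ch, pos, mapq, read_length,
            ifelse(ch == mch, "=", mch), mpos, am)
  }
  f1 <- 0x1 + 0x40 + ifelse(dt$strand1 == "-", 0x10, 0) +
    ifelse(dt$strand2 == "-", 0x20, 0)
  f2 <- 0x1 + 0x80 + ifelse(dt$strand2 == "-", 0x10, 0) +
    ifelse(dt$strand1 == "-", 0x20, 0)
  l1 <- left(dt$pos1, dt$strand1); l2 <- left(dt$pos2, dt$strand2)
  lines <- c(rec(dt$read_name, f1, dt$chrom1, l1, dt$mapq1, dt$chrom2, l2,
                 dt$alt_mapq),
             rec(dt$read_name, f2, dt$chrom2, l2, dt$mapq2, dt$chrom1, l1,
                 dt$alt_mapq))
  ci <- c(match(dt$chrom1, names(chrom_lengths)),
          match(dt$chrom2, names(chrom_lengths)))
  ord <- order(ci, c(l1, l2))
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Read a SAM file back into the pair table dialect
#'
#' Pairs records by read name; secondary/supplementary/unmapped records are
#' skipped with a logged count.
#'
#' @param path SAM path.
#' @param read_length read length (to restore 5'-end positions).
#' @export
read_sam_pairs <- function(path, read_length = 37L) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  f <- data.table::fread(text = paste(ln, collapse = "\n"), sep = "\t",
                         header = FALSE, fill = TRUE)
  flag <- f$V2
  skip <- bitwAnd(flag, 0x4) > 0 | bitwAnd(flag, 0x100) > 0 |
    bitwAnd(flag, 0x800) > 0
  if (any(skip)) message(sprintf("skipped %d unmapped/secondary records",
                                 sum(skip)))
  f <- f[!skip]
  flag <- f$V2
  am <- suppressWarnings(as.integer(sub("^AM:i:", "",
    vapply(seq_len(nrow(f)), function(i) {
      v <- unlist(f[i, -(1:11)])
      hit <- v[startsWith(as.character(v), "AM:i:")]
      if (length(hit)) as.character(hit[1]) else "AM:i:0"
    }, ""))))
  strand <- ifelse(bitwAnd(flag, 0x10) > 0, "-", "+")
  pos5 <- ifelse(strand == "+", f$V4, f$V4 + read_length - 1L)
  first <- bitwAnd(flag, 0x40) > 0
  d <- data.table::data.table(read_name = f$V1, chrom = f$V3,
                              pos = as.integer(pos5), strand = strand,
                              mapq = f$V5, am = am, first = first)
  e1 <- d[first == TRUE]; e2 <- d[first == FALSE]
  m <- merge(e1, e2, by = "read_name", suffixes = c("1", "2"))
  pairs <- m[, list(read_name, chrom1 = chrom1, pos1 = pos1,
                    strand1 = strand1, mapq1 = mapq1, chrom2 = chrom2,
                    pos2 = pos2, strand2 = strand2, mapq2 = mapq2,
                    alt_mapq = pmin(am1, am2))]
  canonicalize_pairs(pairs)
  pairs[]
}

#' Write gene models as GTF
#'
#' Emits gene, transcript, exon and CDS rows (one transcript per gene).
#' The frame column follows GTF semantics: bases to skip before the first
#' complete codon, i.e. `(3 - phase) %% 3` of the internal cumulative
#' phase.
#'
#' @param gene_models exon-level gene model data.frame.
#' @param path output path.
#' @export
write_gtf <- function(gene_models, path) {
  rows <- character()
  attr9 <- function(gid) sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
  for (gid in unique(gene_models$gene_id)) {
    g <- gene_rows(gene_models, gid)
    ch <- g$chrom[1L]; st <- g$strand[1L]
    rows <- c(rows,
      sprintf("%s\tsomaticSV\tgene\t%d\t%d\t.\t%s\t.\t%s", ch, min(g$start),
              max(g$end), st, sprintf('gene_id "%s";', gid)),
      sprintf("%s\tsomaticSV\ttranscript\t%d\t%d\t.\t%s\t.\t%s", ch,
              min(g$start), max(g$end), st, attr9(gid)))
    for (i in seq_len(nrow(g))) {
      rows <- c(rows, sprintf(
        "%s\tsomaticSV\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        ch, g$start[i], g$end[i], st, attr9(gid), g$exon_number[i]))
      if (!is.na(g$cds_start[i])) {
        frame <- (3L - g$phase[i]) %% 3L
        rows <- c(rows, sprintf(
          "%s\tsomaticSV\tCDS\t%d\t%d\t.\t%s\t%d\t%s exon_number \"%d\";",
          ch, g$cds_start[i], g$cds_end[i], st, frame, attr9(gid),
          g$exon_number[i]))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a GTF written by [write_gtf()] back into the exon-level table
#' @param path GTF path.
#' @export
read_gtf <- function(path) {
  f <- read.table(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  names(f) <- c("chrom", "source", "feature", "start", "end", "score",
                "strand", "frame", "attributes")
  getattr <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf('%s "[^"]*"', key), a))
    ifelse(lengths(regmatches(a, gregexpr(sprintf('%s "[^"]*"', key), a))) > 0,
           sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
  }
  ex <- f[f$feature == "exon", ]
  cds <- f[f$feature == "CDS", ]
  ex$gene_id <- getattr(ex$attributes, "gene_id")
  ex$exon_number <- as.integer(getattr(ex$attributes, "exon_number"))
  cds$gene_id <- getattr(cds$attributes, "gene_id")
  cds$exon_number <- as.integer(getattr(cds$attributes, "exon_number"))
  out <- ex[, c("gene_id", "chrom", "strand", "exon_number", "start", "end")]
  key <- paste(out$gene_id, out$exon_number)
  ckey <- paste(cds$gene_id, cds$exon_number)
  out$cds_start <- cds$start[match(key, ckey)]
  out$cds_end <- cds$end[match(key, ckey)]
  out$phase <- (3L - as.integer(cds$frame[match(key, ckey)])) %% 3L
  out <- out[order(out$gene_id, out$exon_number), ]
  rownames(out) <- NULL
  out
}

#' Read an integer copy-number profile (sample, chrom, start, end, cn)
#' @param path TSV path.
#' @export
read_cn_profile <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  names(df)[1:5] <- c("sample_id", "chrom", "start", "end", "cn")
  as.data.frame(df)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  close(con)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = !is.null(comment)))
  invisible(path)
}
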