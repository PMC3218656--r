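gene_rows <- function(gene_models, gid) {
  g <- gene_models[gene_models$gene_id == gid, , drop = FALSE]
  g[order(g$exon_number), ]
}

gene_at <- function(gene_models, chrom, pos) {
  g <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  ids <- unique(g$gene_id)
  hit <- ids[vapply(ids, function(id) {
    gg <- g[g$gene_id == id, ]
    pos >= min(gg$start) && pos <= max(gg$end)
  }, TRUE)]
  if (!length(hit)) return(NULL)
  hit[1L]
}

# breakend side context: which gene, whether exonic, donor/acceptor role,
# and the retained exon set. A "+" breakend retains sequence to its left,
# "-" to its right; a gene transcribing toward the junction donates its 5'
# exons, a gene transcribing away accepts at its 3' exons.
side_context <- function(gene_models, chrom, pos, sigma) {
  gid <- gene_at(gene_models, chrom, pos)
  if (is.null(gid))
    return(list(gene = NULL, role = "intergenic", exonic = FALSE))
  g <- gene_rows(gene_models, gid)
  exonic <- any(pos >= g$start & pos <= g$end)
  tau <- g$strand[1L]
  role <- if (sigma == tau) "donor" else "acceptor"
  retained_left <- sigma == "+"
  ret <- if (retained_left) g$exon_number[g$end < pos]
         else g$exon_number[g$start > pos]
  list(gene = gid, role = role, exonic = exonic, retained = ret, model = g)
}

#' Predict the transcript-level effect of a rearrangement call
#'
#' Maps the two breakends onto gene models and applies the junction
#' geometry: breakends in introns of two genes whose transcriptional
#' orientations become collinear under the event yield a fusion joining the
#' donor's last retained exon to the acceptor's first retained exon; a
#' deletion with both breakends intronic inside one gene yields an
#' internally rearranged transcript; intergenic or orientation-incompatible
#' breakends yield no effect (with a reason code). A breakend inside an
#' exon is reported with `exon_disrupting = TRUE` and frame `NA`.
#'
#' @param call one-row call (needs `event_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`) with base-resolution breakends.
#' @param gene_models exon-level gene model data.frame.
#' @return one-row data.frame `transcript_effect`: `event_id`, `kind`,
#'   `five_gene`, `five_exon`, `three_gene`, `three_exon`, `in_frame`,
#'   `exon_disrupting`, `reason`.
#' @export
predict_effect <- function(call, gene_models) {
  s1 <- side_context(gene_models, call$chrom1, call$pos1, call$strand1)
  s2 <- side_context(gene_models, call$chrom2, call$pos2, call$strand2)
  none <- function(reason) effect_row(call$event_id, "none", reason = reason)
  if (is.null(s1$gene) || is.null(s2$gene)) return(none("intergenic_breakend"))
  if (s1$gene == s2$gene) {
    if (call$chrom1 == call$chrom2 && call$strand1 == "+" &&
        call$strand2 == "-")
      return(predict_internal_deletion_transcript(call,
        gene_rows(gene_models, s1$gene)))
    return(none("intragenic_non_deletion"))
  }
  roles <- c(s1$role, s2$role)
  if (!("donor" %in% roles && "acceptor" %in% roles))
    return(none("orientation_incompatible"))
  don <- if (s1$role == "donor") s1 else s2
  acc <- if (s1$role == "acceptor") s1 else s2
  disrupting <- don$exonic || acc$exonic
  if (!length(don$retained) || !length(acc$retained))
    return(none("no_retained_exons"))
  eff <- effect_row(call$event_id, "fusion",
                    five_gene = don$gene, five_exon = max(don$retained),
                    three_gene = acc$gene, three_exon = min(acc$retained),
                    exon_disrupting = disrupting)
  if (!disrupting)
    eff$in_frame <- determine_frame(eff, gene_models)
  eff
}

effect_row <- function(event_id, kind, five_gene = NA_character_,
                       five_exon = NA_integer_, three_gene = NA_character_,
                       three_exon = NA_integer_, in_frame = NA,
                       exon_disrupting = FALSE, reason = NA_character_) {
  data.frame(event_id = event_id, kind = kind, five_gene = five_gene,
             five_exon = as.integer(five_exon), three_gene = three_gene,
             three_exon = as.integer(three_exon), in_frame = in_frame,
             exon_disrupting = exon_disrupting, reason = reason,
             stringsAsFactors = FALSE)
}

#' Predict the transcript left by a deletion internal to one gene
#'
#' A deletion with intronic breakends inside a single gene splices the exon
#' 5' of the deleted block directly onto the exon 3' of it. A deletion
#' removing the first or last exon is a truncation, not an internal
#' rearrangement; a deletion confined to a single intron leaves the
#' transcript unchanged.
#'
#' @param call one-row deletion call (`+`/`-` breakends, same chromosome).
#' @param gene_model exon rows of the affected gene.
#' @return one-row `transcript_effect` data.frame; for the internal case
#'   the deleted exon numbers are in the `deleted_exons` attribute.
#' @export
predict_internal_deletion_transcript <- function(call, gene_model) {
  g <- gene_model[order(gene_model$exon_number), ]
  lo <- min(call$pos1, call$pos2); hi <- max(call$pos1, call$pos2)
  exonic <- any((lo >= g$start & lo <= g$end) | (hi >= g$start & hi <= g$end))
  deleted <- g$exon_number[g$start > lo & g$end < hi]
  if (!length(deleted))
    return(effect_row(call$event_id, "none", reason = "intronic_deletion",
                      exon_disrupting = exonic))
  if (exonic)
    return(effect_row(call$event_id, "internal_rearrangement",
                      five_gene = g$gene_id[1L], three_gene = g$gene_id[1L],
                      exon_disrupting = TRUE, reason = "exon_disrupted"))
  if (1L %in% deleted || max(g$exon_number) %in% deleted)
    return(effect_row(call$event_id, "truncation",
                      five_gene = g$gene_id[1L], three_gene = g$gene_id[1L],
                      reason = "terminal_exon_lost"))
  eff <- effect_row(call$event_id, "internal_rearrangement",
                    five_gene = g$gene_id[1L], five_exon = min(deleted) - 1L,
                    three_gene = g$gene_id[1L], three_exon = max(deleted) + 1L)
  eff$in_frame <- frame_of_internal_deletion(g, deleted)
  attr(eff, "deleted_exons") <- deleted
  eff
}

cds_width <- function(g, exon_numbers) {
  sel <- g$exon_number %in% exon_numbers & !is.na(g$cds_start)
  if (!any(sel)) return(0L)
  sum(g$cds_end[sel] - g$cds_start[sel] + 1L)
}

frame_of_internal_deletion <- function(g, deleted) {
  if (all(is.na(g$cds_start))) return(NA)
  cds_width(g, deleted) %% 3L == 0L
}

#' Determine whether a predicted effect is in frame
#'
#' For fusions: in frame iff the coding phase at the donor junction (total
#' retained donor coding length mod 3) equals the phase expected at the
#' acceptor's first retained exon. A donor contributing only untranslated
#' exons is in frame iff the acceptor retains its own start codon (a single
#' ORF then spans the junction); a coding donor joined into acceptor UTR is
#' out of frame. For internal rearrangements: in frame iff the deleted
#' coding length is a multiple of 3. Non-coding genes give `NA`.
#'
#' @param effect one-row `transcript_effect`.
#' @param gene_models exon-level gene model data.frame.
#' @return logical (or `NA`).
#' @export
determine_frame <- function(effect, gene_models) {
  if (effect$kind == "internal_rearrangement") {
    g <- gene_rows(gene_models, effect$five_gene)
    deleted <- seq(effect$five_exon + 1L, effect$three_exon - 1L)
    return(frame_of_internal_deletion(g, deleted))
  }
  if (effect$kind != "fusion") return(NA)
  don <- gene_rows(gene_models, effect$five_gene)
  acc <- gene_rows(gene_models, effect$three_gene)
  if (all(is.na(don$cds_start)) && all(is.na(acc$cds_start))) return(NA)
  don_len <- cds_width(don, seq_len(effect$five_exon))
  acc_coding <- acc$exon_number[!is.na(acc$cds_start)]
  if (!length(acc_coding)) return(NA)
  if (don_len == 0L) {
    # untranslated donor: ORF spans the junction iff the acceptor keeps
    # its own start codon
    return(min(acc_coding) >= effect$three_exon)
  }
  first_ret <- effect$three_exon
  if (!first_ret %in% acc_coding) {
    # coding donor spliced into acceptor UTR: no continuous ORF
    return(FALSE)
  }
  acc_phase <- acc$phase[acc$exon_number == first_ret]
  (don_len %% 3L) == acc_phase
}
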