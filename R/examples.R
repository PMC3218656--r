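# Worked-example simulations mirroring the published tumor geometries.
# Both place implanted junctions in uniquely mappable sequence (the repeat
# mask is scrubbed within 2 kb of each breakpoint): the events they emulate
# were PCR-validated at base resolution and by construction live in
# mappable regions.

clear_mask_near <- function(mask, chrom, points, slop = 2000L) {
  if (is.null(mask) || nrow(mask) == 0L) return(mask)
  drop <- rep(FALSE, nrow(mask))
  for (p in points) {
    drop <- drop | (mask$chrom == chrom & mask$start <= p + slop &
                      mask$end >= p - slop)
  }
  mask[!drop, , drop = FALSE]
}

n_pairs_for_coverage <- function(coverage, genome_length, cfg_frag = c(400, 450, 550)) {
  mean_frag <- sum(cfg_frag) / 3
  as.integer(round(coverage * genome_length / mean_frag))
}

#' Simulate the Cre-deletion size-ladder tumor
#'
#' A 10-Mb single-chromosome tumor carrying four homozygous somatic
#' deletions of 20 kb, 14 kb, 8 kb and 7 kb — the sizes of the engineered
#' Brca1, Cdh1, Trp53 and Brca2 conditional-allele deletions. At the
#' default physical coverage the 20- and 14-kb deletions exceed the 10-kb
#' calling criterion with multiple spanning pairs, while the 8- and 7-kb
#' deletions fall below it and are not expected to be called.
#'
#' @param seed master seed.
#' @param coverage target physical coverage (fragment span per base).
#' @return implanted `synthetic_dataset` with simulated reads.
#' @export
simulate_cre_ladder_tumor <- function(seed = 1L, coverage = 10) {
  L <- 10000000L
  cfg <- sim_config(genome_length_per_chrom = L, n_chroms = 1L,
                    n_pairs = n_pairs_for_coverage(coverage, L),
                    gap_length = 20000L, n_germline_sv = 0L, seed = seed)
  ds <- simulate_genome(cfg)
  ev <- rbind(
    truth_event("deletion", "chr1", 3000001L, 3020000L, microhomology = 2L,
                homozygous = TRUE),   # Brca1-like, 20 kb
    truth_event("deletion", "chr1", 4500001L, 4514000L, microhomology = 1L,
                homozygous = TRUE),   # Cdh1-like, 14 kb
    truth_event("deletion", "chr1", 6000001L, 6008000L, homozygous = TRUE),
    truth_event("deletion", "chr1", 7500001L, 7507000L, homozygous = TRUE))
  pts <- c(ev$pos1, ev$pos2)
  ds$masks$repeats <- clear_mask_near(ds$masks$repeats, "chr1", pts)
  ds <- implant_events(ds, ev)
  suppressMessages(simulate_read_pairs(ds))
}

#' Simulate the two fusion-generating rearrangements
#'
#' A 13-Mb chromosome carrying (i) a 200-kb tandem duplication whose
#' everted junction joins intron 2 of a downstream donor gene onto intron 1
#' of an upstream acceptor gene (the exon 2 - exon 2 fusion geometry), and
#' (ii) an 8-Mb deletion joining intron 6 of a donor gene to intron 4 of an
#' acceptor gene (the exon 6 - exon 5 fusion geometry). Gene models are
#' placed so the implanted breakends fall in the stated introns; both
#' events are somatic and homozygous.
#'
#' @param seed master seed.
#' @param coverage target physical coverage.
#' @return implanted `synthetic_dataset` with simulated reads.
#' @export
simulate_fusion_tumor <- function(seed = 1L, coverage = 10) {
  L <- 13000000L
  cfg <- sim_config(genome_length_per_chrom = L, n_chroms = 1L,
                    n_pairs = n_pairs_for_coverage(coverage, L),
                    gap_length = 20000L, n_genes = 0L, n_germline_sv = 0L,
                    seed = seed)
  ds <- simulate_genome(cfg)

  s <- 1800000L                      # tandem duplication [s, e], 200 kb
  e <- s + 200000L
  posL <- 3500000L                   # deletion breakends, 8 Mb apart
  posR <- posL + 8000000L

  # 201-bp exons with a 10-bp UTR trim keep every junction phase equal, so
  # both fusions are predicted in frame, as in the tumors they emulate
  gene <- function(id, origin, n_ex, exon_w = 201L, intron_gap = 3000L)
    make_gene_model(id, "chr1", "+",
                    exon_starts = origin + (seq_len(n_ex) - 1L) * intron_gap + 1L,
                    exon_widths = rep(exon_w, n_ex),
                    cds_from = 1L, cds_to = n_ex)
  # acceptor for the duplication: s lies in intron 1
  acc_td <- gene("fusB_acceptor", s - 1600L, 8L)
  # donor for the duplication: e lies in intron 2
  don_td <- gene("fusA_donor", e - 4600L, 5L)
  # deletion donor: posL lies in intron 6; acceptor: posR in intron 4
  don_del <- gene("fusC_donor", posL - 16600L, 9L)
  acc_del <- gene("fusD_acceptor", posR - 10600L, 9L)
  ds$gene_models <- rbind(acc_td, don_td, don_del, acc_del)

  stopifnot(in_intron(acc_td, s, 1L), in_intron(don_td, e, 2L),
            in_intron(don_del, posL, 6L), in_intron(acc_del, posR, 4L))

  ev <- rbind(
    truth_event("tandem_duplication", "chr1", s, e, homozygous = TRUE),
    truth_event("deletion", "chr1", posL + 1L, posR - 1L, homozygous = TRUE))
  pts <- c(s, e, posL, posR)
  ds$masks$repeats <- clear_mask_near(ds$masks$repeats, "chr1", pts)
  ds <- implant_events(ds, ev)
  suppressMessages(simulate_read_pairs(ds))
}

in_intron <- function(g, pos, intron_number) {
  g <- g[order(g$exon_number), ]
  pos > g$end[g$exon_number == intron_number] &&
    pos < g$start[g$exon_number == intron_number + 1L]
}
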