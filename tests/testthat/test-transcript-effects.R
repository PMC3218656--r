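mk_call <- function(pos1, pos2, strand1, strand2, chrom = "toy",
                    id = "ev1") {
  list(event_id = id, chrom1 = chrom, pos1 = pos1, strand1 = strand1,
       chrom2 = chrom, pos2 = pos2, strand2 = strand2)
}

intron_pos <- function(g, after_exon) {
  g <- g[order(g$exon_number), ]
  (g$end[g$exon_number == after_exon] +
     g$start[g$exon_number == after_exon + 1L]) %/% 2L
}

test_that("tandem duplication fuses donor intron 2 to acceptor intron 1", {
  tg <- toy_gene_genome(seed = 2)
  # everted junction of a duplication spanning [s, e]: sequence ending at e
  # (geneB intron 2, the donor side) is joined back onto sequence starting
  # at s (geneA intron 1, the acceptor side)
  s_a <- intron_pos(tg$a, 1L)
  e_b <- intron_pos(tg$b, 2L)
  call <- mk_call(s_a, e_b, "-", "+")
  eff <- predict_effect(call, tg$models)
  expect_equal(eff$kind, "fusion")
  expect_equal(eff$five_gene, "geneB")
  expect_equal(eff$five_exon, 2L)
  expect_equal(eff$three_gene, "geneA")
  expect_equal(eff$three_exon, 2L)
})

test_that("deletion fuses donor intron 6 to acceptor intron 4", {
  tg <- toy_gene_genome(seed = 3)
  call <- mk_call(intron_pos(tg$a, 6L), intron_pos(tg$b, 4L), "+", "-")
  eff <- predict_effect(call, tg$models)
  expect_equal(eff$kind, "fusion")
  expect_equal(eff$five_gene, "geneA")
  expect_equal(eff$five_exon, 6L)
  expect_equal(eff$three_gene, "geneB")
  expect_equal(eff$three_exon, 5L)
  expect_equal(eff$in_frame,
               oracle_fusion_in_frame(tg$genome, tg$a, tg$b, 6L, 5L))
})

test_that("intergenic and orientation-incompatible breakends yield no effect", {
  tg <- toy_gene_genome(seed = 4)
  eff <- predict_effect(mk_call(100L, 31000L, "+", "-"), tg$models)
  expect_equal(eff$kind, "none")
  expect_equal(eff$reason, "intergenic_breakend")
  # two donors: inversion-type junction between two same-strand genes
  eff2 <- predict_effect(mk_call(intron_pos(tg$a, 2L), intron_pos(tg$b, 2L),
                                 "+", "+"), tg$models)
  expect_equal(eff2$kind, "none")
  expect_equal(eff2$reason, "orientation_incompatible")
})

test_that("exonic breakends are reported as disrupting with frame NA", {
  tg <- toy_gene_genome(seed = 5)
  inside_exon <- tg$a$start[tg$a$exon_number == 3L] + 5L
  eff <- predict_effect(mk_call(inside_exon, intron_pos(tg$b, 4L), "+", "-"),
                        tg$models)
  expect_true(eff$exon_disrupting)
  expect_true(is.na(eff$in_frame))
})

test_that("internal deletions join the flanking exons (58-exon geometry)", {
  big <- make_gene_model("lrp1b_like", "toy", "+",
                         exon_starts = 1000L + (0:57) * 1500L,
                         exon_widths = rep(120L, 58L),
                         cds_from = 1L, cds_to = 58L)
  p1 <- intron_pos(big, 3L); p2 <- intron_pos(big, 11L)
  eff <- predict_internal_deletion_transcript(
    mk_call(p1, p2, "+", "-"), big)
  expect_equal(eff$kind, "internal_rearrangement")
  expect_equal(eff$five_exon, 3L)
  expect_equal(eff$three_exon, 12L)
  expect_equal(attr(eff, "deleted_exons"), 4:11)

  # deletion inside one intron: transcript unchanged
  mid <- intron_pos(big, 5L)
  eff2 <- predict_internal_deletion_transcript(
    mk_call(mid - 100L, mid + 100L, "+", "-"), big)
  expect_equal(eff2$kind, "none")

  # removing the first exon is a truncation
  eff3 <- predict_internal_deletion_transcript(
    mk_call(500L, intron_pos(big, 2L), "+", "-"), big)
  expect_equal(eff3$kind, "truncation")

  # toy 5-exon case: deleting exons 2-3 joins exon 1 to exon 4
  toy5 <- make_gene_model("toy5", "toy", "+",
                          exon_starts = c(100L, 600L, 1100L, 1600L, 2100L),
                          exon_widths = rep(90L, 5L))
  eff4 <- predict_internal_deletion_transcript(
    mk_call(intron_pos(toy5, 1L), intron_pos(toy5, 3L), "+", "-"), toy5)
  expect_equal(eff4$five_exon, 1L)
  expect_equal(eff4$three_exon, 4L)
})

test_that("frame rule: deleted coding length mod 3", {
  # exon CDS widths 80 x 3 = 240 -> in frame; 241 -> not
  g240 <- make_gene_model("g", "toy", "+",
                          exon_starts = c(100, 600, 1100, 1600, 2100),
                          exon_widths = c(100, 80, 80, 80, 100))
  g240$cds_start <- g240$start; g240$cds_end <- g240$end
  g240$phase <- cumsum(c(0, head(g240$end - g240$start + 1, -1))) %% 3
  del <- 2:4
  expect_true(frame_of_internal_deletion(g240, del))       # 240 %% 3 == 0
  g241 <- g240; g241$cds_end[2] <- g241$cds_end[2] + 1L
  g241$end[2] <- g241$end[2] + 1L
  expect_false(frame_of_internal_deletion(g241, del))      # 241 %% 3 != 0
})

test_that("determine_frame agrees with the translation oracle on random models", {
  set.seed(99)
  n_agree <- 0L; n_total <- 0L
  for (rep in 1:25) {
    tg <- toy_gene_genome(seed = 1000L + rep)
    # random fusion: donor exon k of geneA to acceptor exon j of geneB
    k <- sample(1:7, 1); j <- sample(2:8, 1)
    eff <- effect_row("e", "fusion", five_gene = "geneA", five_exon = k,
                      three_gene = "geneB", three_exon = j)
    got <- determine_frame(eff, tg$models)
    want <- oracle_fusion_in_frame(tg$genome, tg$a, tg$b, k, j)
    n_total <- n_total + 1L
    n_agree <- n_agree + as.integer(identical(got, want))
    # random internal deletion of geneA
    d1 <- sample(2:5, 1); d2 <- sample(d1:6, 1)
    eff2 <- effect_row("e2", "internal_rearrangement", five_gene = "geneA",
                       five_exon = d1 - 1L, three_gene = "geneA",
                       three_exon = d2 + 1L)
    got2 <- determine_frame(eff2, tg$models)
    want2 <- oracle_deletion_in_frame(tg$genome, tg$a, d1:d2)
    n_total <- n_total + 1L
    n_agree <- n_agree + as.integer(identical(got2, want2))
  }
  expect_equal(n_agree, n_total)
})

test_that("effect_row internals are exposed consistently via determine_frame", {
  # phase-1 donor joined to phase-2 acceptor is out of frame, and the
  # translation oracle on the reconstructed sequence agrees
  tg <- toy_gene_genome(seed = 7)
  phases_b <- tg$b$phase
  j <- which(phases_b == 2L)[1]
  skip_if(is.na(j), "no phase-2 exon in this toy model")
  dons <- vapply(1:7, function(k) {
    don_len <- sum(tg$a$cds_end[1:k] - tg$a$cds_start[1:k] + 1L)
    don_len %% 3L
  }, 0L)
  k <- which(dons == 1L)[1]
  skip_if(is.na(k), "no phase-1 donor prefix in this toy model")
  eff <- effect_row("e", "fusion", five_gene = "geneA", five_exon = k,
                    three_gene = "geneB", three_exon = tg$b$exon_number[j])
  expect_false(determine_frame(eff, tg$models))
  expect_false(oracle_fusion_in_frame(tg$genome, tg$a, tg$b, k,
                                      tg$b$exon_number[j]))
})
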