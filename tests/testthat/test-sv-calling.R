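test_that("discordant clustering groups by geometry and counts independence", {
  p <- make_pairs(
    make_pair(pos1 = 10000, pos2 = 30000, read_name = "a"),
    make_pair(pos1 = 10100, pos2 = 30100, read_name = "b"),
    make_pair(pos1 = 10050, pos2 = 30050, strand1 = "-", strand2 = "+",
              read_name = "everted"))
  cl <- cluster_discordant_pairs(p)
  expect_equal(nrow(cl$clusters), 2L)
  main <- cl$clusters[strand1 == "+"]
  expect_equal(main$n_independent, 2L)

  # identical position tuples are not independent
  p2 <- make_pairs(
    make_pair(pos1 = 10000, pos2 = 30000, read_name = "a"),
    make_pair(pos1 = 10000, pos2 = 30000, read_name = "b"),
    make_pair(pos1 = 10200, pos2 = 30200, read_name = "c"))
  cl2 <- cluster_discordant_pairs(p2)
  expect_equal(nrow(cl2$clusters), 1L)
  expect_equal(cl2$clusters$n_pairs, 3L)
  expect_equal(cl2$clusters$n_independent, 2L)

  # far-apart pairs split
  p3 <- make_pairs(make_pair(pos1 = 10000, pos2 = 30000, read_name = "a"),
                   make_pair(pos1 = 20000, pos2 = 40000, read_name = "b"))
  expect_equal(nrow(cluster_discordant_pairs(p3)$clusters), 2L)
})

test_that("criteria are evaluated in order with the stated thresholds", {
  cfg <- pipeline_config()
  seg <- data.frame(chrom = c("chr1", "chr1"), start = c(1L, 100001L),
                    end = c(100000L, 5000000L), mean_density = c(10, 20),
                    n_bins = c(7L, 300L))
  mk_cluster <- function(pos1, pos2, n_ind, altq, chrom2 = "chr1") {
    data.table::data.table(cluster_id = 1L, chrom1 = "chr1", chrom2 = chrom2,
      strand1 = "+", strand2 = "-", be1 = pos1, be2 = pos2,
      n_pairs = n_ind, n_independent = n_ind, max_alt_quality = altq,
      read_name = "x", span = if (chrom2 == "chr1") abs(pos2 - pos1) else NA_integer_)
  }
  # criterion 1: >= 10 kb, >= 2 independent, alt quality present
  c1 <- evaluate_criteria(mk_cluster(1e6, 1e6 + 15000, 2L, 60L), seg, cfg)
  expect_equal(c1$criterion, 1L)
  # criterion 2: single pair near a change point (boundary at 100001)
  c2 <- evaluate_criteria(mk_cluster(60000, 150000, 1L, 40L), seg, cfg)
  expect_equal(c2$criterion, 2L)
  # single pair, no change point within 100 kb: no call
  c_none <- evaluate_criteria(mk_cluster(1e6, 1e6 + 15000, 1L, 40L), seg, cfg)
  expect_equal(nrow(c_none), 0L)
  # criterion 3: 600 bp - 10 kb with change-point support and 2 pairs
  c3 <- evaluate_criteria(mk_cluster(95000, 103000, 2L, 60L), seg, cfg)
  expect_equal(c3$criterion, 3L)
  # criterion 4 is opt-in
  c4_off <- evaluate_criteria(mk_cluster(1e6, 1e6 + 8000, 2L, 60L), seg, cfg)
  expect_equal(nrow(c4_off), 0L)
  cfg4 <- pipeline_config(enable_criterion4 = TRUE)
  c4_on <- evaluate_criteria(mk_cluster(1e6, 1e6 + 8000, 2L, 60L), seg, cfg4)
  expect_equal(c4_on$criterion, 4L)
  # interchromosomal clusters satisfy the span condition vacuously
  tra <- evaluate_criteria(mk_cluster(1e6, 2e6, 2L, 60L, chrom2 = "chr2"),
                           seg, cfg)
  expect_equal(tra$criterion, 1L)
  # below the alternative-quality floor: never called
  lowq <- evaluate_criteria(mk_cluster(1e6, 1e6 + 15000, 2L, 34L), seg, cfg)
  expect_equal(nrow(lowq), 0L)
  expect_error(evaluate_criteria(mk_cluster(1e6, 1.1e6, 2L, 60L), NULL, cfg),
               "segments")
})

test_that("event types follow breakend geometry", {
  expect_equal(classify_event("chr1", "chr1", "+", "-"), "deletion")
  expect_equal(classify_event("chr1", "chr1", "-", "+"), "tandem_duplication")
  expect_equal(classify_event("chr1", "chr1", "+", "+"), "inversion")
  expect_equal(classify_event("chr1", "chr2", "+", "-"), "interchromosomal")
})

test_that("simulated events produce the expected cluster geometry end to end", {
  ds <- tiny_dataset()
  cfg <- pipeline_config(gap_exclusion = 100000L, seed = 2)
  ft <- filter_pairs(ds$tumor_pairs, ds$masks, cfg)
  fn <- filter_pairs(ds$normal_pairs, ds$masks, cfg)
  bins <- build_mappable_bins(ds$reference, ds$masks$repeats, ds$masks$gaps)
  bins <- count_pairs_in_bins(ft$concordant, bins)
  seg <- segment_copy_number(bins, seed = 2)
  calls <- call_rearrangements(ft$discordant, seg, cfg,
                               normal_discordant = fn$discordant)
  truth_idx <- match_calls_to_truth(calls, ds$truth, window = cfg$cluster_window)
  matched <- ds$truth[truth_idx[!is.na(truth_idx)], ]
  # every somatic event with span > 10 kb and >= 2 surviving independent
  # spanning pairs is recovered with the right type
  big <- ds$truth[ds$truth$somatic & !is.na(ds$truth$span) &
                    ds$truth$span > 10000, ]
  support <- vapply(seq_len(nrow(big)), function(i) {
    ev <- big[i, ]
    hits <- ft$discordant[chrom1 == ev$chrom1 & chrom2 == ev$chrom2 &
                            strand1 == ev$strand1 & strand2 == ev$strand2 &
                            abs(pos1 - ev$pos1) <= cfg$cluster_window &
                            abs(pos2 - ev$pos2) <= cfg$cluster_window]
    data.table::uniqueN(paste(hits$pos1, hits$pos2))
  }, 0L)
  expect_gt(sum(support >= 2), 0)   # the fixture must exercise the check
  expect_true(all(big$event_id[support >= 2] %in% matched$event_id))
  for (i in which(!is.na(truth_idx))) {
    want <- ds$truth$event_type[truth_idx[i]]
    if (want == "amplification") want <- "tandem_duplication"
    expect_equal(calls$event_type[i], want)
  }
  # germline events are subtracted via the matched normal
  germ <- ds$truth[!ds$truth$somatic, ]
  expect_false(any(match_calls_to_truth(calls, germ, cfg$cluster_window) > 0,
                   na.rm = TRUE))
  # no called member pair overlaps a removal reason (pipeline ordering)
  members <- cluster_discordant_pairs(ft$discordant, cfg$cluster_window)$members
  removed_names <- ft$outcomes[status == "removed"]$read_name
  expect_equal(length(intersect(members$read_name, removed_names)), 0L)
})

test_that("amplicon association uses the >= threshold on segment density", {
  # median bin density 10; the middle segment sits at 8x
  seg <- data.frame(chrom = "chr1",
                    start = c(1, 1e6 + 1, 1.2e6 + 1),
                    end = c(1e6, 1.2e6, 3e6),
                    mean_density = c(10, 80, 10), n_bins = c(67, 13, 120))
  calls <- data.table::data.table(chrom1 = "chr1", be1 = c(1.1e6, 0.5e6),
                                  chrom2 = "chr1", be2 = c(2.5e6, 0.6e6))
  f <- flag_amplicon_association(calls, seg, amplification_threshold = 5)
  expect_equal(f$amplicon_associated, c(TRUE, FALSE))
  # boundary: a segment exactly at threshold x median is flagged (>=)
  seg$mean_density <- c(10, 50, 10)
  f2 <- flag_amplicon_association(calls, seg, 5)
  expect_true(f2$amplicon_associated[1L])
})
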