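test_that("pair classification follows orientation and span", {
  p <- make_pairs(
    make_pair(pos1 = 1000, pos2 = 1450, read_name = "conc"),
    make_pair(pos1 = 1000, pos2 = 21450, read_name = "del20kb"),
    make_pair(pos1 = 1000, pos2 = 5000, chrom2 = "chr2", read_name = "tra"),
    make_pair(pos1 = 1000, pos2 = 1450, strand1 = "-", strand2 = "+",
              read_name = "everted"))
  expect_equal(classify_pair(p),
               c("concordant", "discordant", "discordant", "discordant"))
  # boundary: span exactly at the ceiling is concordant
  expect_equal(classify_pair(make_pair(pos1 = 1, pos2 = 601)), "concordant")
  expect_equal(classify_pair(make_pair(pos1 = 1, pos2 = 602)), "discordant")
})

test_that("PCR duplicate removal keeps the highest-quality pair", {
  p <- make_pairs(
    make_pair(pos1 = 1000, pos2 = 1450, mapq1 = 60, mapq2 = 60, read_name = "hi"),
    make_pair(pos1 = 1001, pos2 = 1449, mapq1 = 40, mapq2 = 40, read_name = "lo"))
  r <- remove_pcr_duplicates(p)
  expect_equal(r$records$read_name, "hi")
  expect_equal(r$removed_count, 1L)

  # 2 bp apart: outside the +/-1 window, both retained
  p2 <- make_pairs(make_pair(pos1 = 1000, pos2 = 1450, read_name = "a"),
                   make_pair(pos1 = 1002, pos2 = 1450, read_name = "b"))
  expect_equal(remove_pcr_duplicates(p2)$removed_count, 0L)

  # 10 exact copies -> 1 retained
  p3 <- do.call(make_pairs, lapply(1:10, function(i)
    make_pair(pos1 = 5000, pos2 = 5400, read_name = sprintf("c%02d", i))))
  r3 <- remove_pcr_duplicates(p3)
  expect_equal(nrow(r3$records), 1L)
  expect_equal(r3$removed_count, 9L)
  expect_equal(r3$records$read_name, "c01")  # deterministic tie-break
})

test_that("duplicate removal matches the brute-force oracle on random fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200
    recs <- data.table::rbindlist(lapply(seq_len(n), function(i) {
      p1 <- sample(1000:1100, 1)  # tight range to force many collisions
      make_pair(pos1 = p1, pos2 = p1 + sample(380:420, 1),
                mapq1 = sample(10:60, 1), mapq2 = sample(10:60, 1),
                read_name = sprintf("r%03d", i))
    }))
    got <- sort(remove_pcr_duplicates(recs)$records$read_name)
    expect_identical(got, oracle_duplicates(recs))
  }
})

test_that("region filters remove by repeat, gap proximity and germline proximity", {
  repeats <- data.frame(chrom = "chr1", start = 5000, end = 5300)
  gaps <- data.frame(chrom = "chr1", start = 1, end = 10000)
  germ <- data.frame(chrom = "chr1", start = 5e6, end = 5.02e6)
  p <- make_pairs(
    make_pair(pos1 = 5100, pos2 = 5550, read_name = "in_sine"),
    make_pair(pos1 = 910000, pos2 = 910450, read_name = "near_gap"),
    make_pair(pos1 = 5000501, pos2 = 5020501, read_name = "germ_out"),
    make_pair(pos1 = 5000400, pos2 = 5020400, read_name = "germ_in"),
    make_pair(pos1 = 3e6, pos2 = 3000450, read_name = "clean"))
  r <- apply_region_filters(p, repeats, gaps, germ)
  res <- setNames(r$removed$removal_reason, r$removed$read_name)
  expect_equal(res[["in_sine"]], "repeat_overlap")
  expect_equal(res[["near_gap"]], "gap_proximity")
  expect_equal(res[["germ_in"]], "germline_sv_proximity")
  # both ends 501 bp away: retained (boundary just outside 500)
  expect_true(all(c("germ_out", "clean") %in% r$records$read_name))
  expect_warning(
    apply_region_filters(p, data.frame(chrom = "chrUn", start = 1, end = 10)),
    "unknown chromosome")
})

test_that("inverted singletons are removed unless independently supported", {
  p <- make_pairs(
    make_pair(pos1 = 1000, pos2 = 1300, strand1 = "-", strand2 = "+",
              read_name = "lone"),
    make_pair(pos1 = 50000, pos2 = 50300, strand1 = "-", strand2 = "+",
              read_name = "sup1"),
    make_pair(pos1 = 50010, pos2 = 50320, strand1 = "-", strand2 = "+",
              read_name = "sup2"),
    make_pair(pos1 = 90000, pos2 = 90600, strand1 = "-", strand2 = "+",
              read_name = "long600"))
  r <- remove_inverted_singletons(p)
  expect_equal(r$removed$read_name, "lone")
  expect_true(all(c("sup1", "sup2", "long600") %in% r$records$read_name))
})

test_that("the full cascade partitions records and is idempotent", {
  ds <- tiny_dataset()
  cfg <- pipeline_config(gap_exclusion = 100000L)
  res <- filter_pairs(ds$tumor_pairs, ds$masks, cfg)
  expect_equal(nrow(res$outcomes), nrow(ds$tumor_pairs))
  expect_false(any(duplicated(res$outcomes$read_name)))
  expect_true(all(is.na(res$outcomes$removal_reason) ==
                    (res$outcomes$status != "removed")))
  n_removed <- sum(res$outcomes$status == "removed")
  expect_equal(sum(unlist(res$counts)), n_removed)
  expect_equal(nrow(res$concordant) + nrow(res$discordant) + n_removed,
               nrow(ds$tumor_pairs))

  # idempotence: re-running on the retained set removes nothing
  kept <- res$outcomes[status != "removed",
                       !c("status", "removal_reason"), with = FALSE]
  res2 <- filter_pairs(kept, ds$masks, cfg)
  expect_equal(sum(res2$outcomes$status == "removed"), 0L)
  expect_equal(sort(res2$outcomes$read_name), sort(kept$read_name))
})

test_that("removed duplicate fraction tracks the configured rate", {
  ds <- tiny_dataset()
  d <- ds$config$duplicate_rate
  n <- ds$config$n_pairs
  res <- remove_pcr_duplicates(ds$tumor_pairs)
  frac <- res$removed_count / n
  se <- sqrt(d * (1 - d) / n)
  expect_lt(abs(frac - d), 3 * se + 2 / sqrt(n))
})

test_that("low-confidence floor removes pairs when enabled", {
  p <- make_pairs(make_pair(pos1 = 1e6, pos2 = 1.2e6, alt_mapq = 10,
                            read_name = "low"),
                  make_pair(pos1 = 2e6, pos2 = 2.2e6, alt_mapq = 60,
                            read_name = "high"))
  cfg <- pipeline_config(min_low_confidence = 35L)
  res <- filter_pairs(p, list(), cfg)
  expect_equal(res$outcomes[read_name == "low"]$removal_reason,
               "low_confidence_mapping")
  expect_equal(res$outcomes[read_name == "high"]$status,
               "retained_discordant")
})
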