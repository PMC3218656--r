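test_that("file formats round-trip", {
  td <- withr::local_tempdir()
  ds <- tiny_dataset()

  fa <- file.path(td, "ref.fa")
  write_fasta(ds$reference, fa)
  expect_identical(read_fasta(fa), ds$reference)

  bed <- file.path(td, "rep.bed")
  write_bed(ds$masks$repeats, bed)
  expect_equal(read_bed(bed), ds$masks$repeats)

  gtf <- file.path(td, "genes.gtf")
  write_gtf(ds$gene_models, gtf)
  back <- read_gtf(gtf)
  orig <- ds$gene_models[order(ds$gene_models$gene_id,
                               ds$gene_models$exon_number), ]
  rownames(orig) <- NULL
  expect_equal(back$start, orig$start)
  expect_equal(back$cds_start, orig$cds_start)
  expect_equal(back$phase[!is.na(back$phase)],
               orig$phase[!is.na(orig$phase)])

  tsv <- file.path(td, "pairs.tsv")
  sub <- ds$tumor_pairs[1:500]
  write_pairs_tsv(sub, tsv)
  expect_equal(as.data.frame(read_pairs_tsv(tsv)), as.data.frame(sub))

  sam <- file.path(td, "pairs.sam")
  write_sam(sub, nchar(ds$reference), sam)
  got <- read_sam_pairs(sam)
  got <- as.data.frame(got[order(read_name),
    list(read_name, chrom1, pos1, strand1, chrom2, pos2, strand2)])
  want <- as.data.frame(sub[order(read_name),
    list(read_name, chrom1, pos1, strand1, chrom2, pos2, strand2)])
  expect_equal(got, want)
})

test_that("pipeline runs are deterministic and manifests reconcile", {
  ds <- tiny_dataset()
  cfg <- pipeline_config(gap_exclusion = 100000L, seed = 4)
  r1 <- run_pipeline(ds, cfg)
  r2 <- run_pipeline(ds, cfg)
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$segments, r2$segments)
  m <- r1$manifest
  expect_equal(m$counts$tumor_pairs_in,
               m$counts$tumor_retained_concordant +
                 m$counts$tumor_retained_discordant +
                 sum(unlist(m$counts$tumor_removed)))
})

test_that("run directory contains every stage output", {
  td <- withr::local_tempdir()
  ds <- tiny_dataset()
  cfg <- pipeline_config(gap_exclusion = 100000L, seed = 4)
  run_pipeline(ds, cfg, outdir = td)
  for (f in c("tumor_filter_outcomes.tsv", "bins.tsv", "segments.tsv",
              "calls.bedpe", "calls.tsv", "call_type_counts.tsv",
              "junction_signatures.tsv", "junction_histogram.tsv",
              "manifest.json"))
    expect_true(file.exists(file.path(td, f)), label = f)
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(man$counts$n_calls, nrow(run_pipeline(ds, cfg)$calls))
})

test_that("the CLI simulates, filters and scans from files", {
  td <- withr::local_tempdir()
  cfgfile <- file.path(td, "sim.cfg")
  writeLines(c("genome_length_per_chrom = 300000", "n_chroms = 1",
               "n_pairs = 3000", "gap_length = 2000", "n_genes = 2",
               "gap_exclusion = 20000"), cfgfile)
  suppressMessages(sv_cli(c("simulate", "--config", cfgfile, "--seed", "5",
                            "--outdir", file.path(td, "sim"))))
  expect_true(file.exists(file.path(td, "sim", "reference.fa")))
  expect_true(file.exists(file.path(td, "sim", "tumor.sam")))

  # filter requires the gap mask under the default 1-Mb exclusion
  expect_error(
    sv_cli(c("filter", "--pairs", file.path(td, "sim", "tumor_pairs.tsv"))),
    "gap")
  suppressMessages(sv_cli(c("filter",
    "--pairs", file.path(td, "sim", "tumor_pairs.tsv"),
    "--config", cfgfile,
    "--repeat-bed", file.path(td, "sim", "repeats.bed"),
    "--gap-bed", file.path(td, "sim", "gaps.bed"),
    "--germline-bed", file.path(td, "sim", "germline_sv.bed"),
    "--outdir", file.path(td, "filt"))))
  expect_true(file.exists(file.path(td, "filt", "discordant.tsv")))
  expect_true(file.exists(file.path(td, "filt", "removals.tsv")))

  # cn on the full pair table, call on the filtered discordant pairs
  suppressMessages(sv_cli(c("cn",
    "--pairs", file.path(td, "sim", "tumor_pairs.tsv"),
    "--reference", file.path(td, "sim", "reference.fa"),
    "--repeat-bed", file.path(td, "sim", "repeats.bed"),
    "--gap-bed", file.path(td, "sim", "gaps.bed"),
    "--config", cfgfile, "--seed", "5",
    "--outdir", file.path(td, "cn"))))
  expect_true(file.exists(file.path(td, "cn", "segments.tsv")))
  suppressMessages(sv_cli(c("call",
    "--pairs", file.path(td, "filt", "discordant.tsv"),
    "--segments", file.path(td, "cn", "segments.tsv"),
    "--config", cfgfile, "--seed", "5",
    "--outdir", file.path(td, "call"))))
  expect_true(file.exists(file.path(td, "call", "calls.tsv")))

  # junction scoring from FASTA + event table
  ds <- tiny_dataset()
  evs <- ds$truth[ds$truth$event_type %in%
                    c("deletion", "tandem_duplication"), ]
  obs <- do.call(rbind, lapply(seq_len(nrow(evs)), function(i)
    junction_observation(ds, evs[i, ], width = 10)))
  jfa <- file.path(td, "junctions.fa")
  write_fasta(setNames(obs$junction, obs$event_id), jfa)
  rfa <- file.path(td, "ref2.fa")
  write_fasta(ds$reference, rfa)
  etsv <- file.path(td, "events.tsv")
  ev_out <- evs[, c("event_id", "chrom1", "pos1", "strand1", "chrom2",
                    "pos2", "strand2")]
  write.table(ev_out, etsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- suppressMessages(sv_cli(c("junctions", "--fasta", jfa,
    "--reference", rfa, "--events", etsv,
    "--outdir", file.path(td, "junc"))))
  expect_equal(sig$microhomology_length, evs$microhomology_length)
  expect_equal(sig$non_templated, evs$non_templated)
  expect_true(file.exists(file.path(td, "junc", "junction_histogram.tsv")))

  co <- lrp1b_cohort(n_samples = 50L)
  ptsv <- file.path(td, "profile.tsv")
  write.table(co$profile, ptsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gtf <- file.path(td, "lrp1b.gtf")
  write_gtf(co$gene, gtf)
  out <- file.path(td, "exondel.tsv")
  sv_cli(c("exonscan", "--profile", ptsv, "--gtf", gtf, "--out", out))
  expect_true(file.exists(out))
  got <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(nrow(got), 32L)
})

test_that("identical config and seed give byte-identical simulate output", {
  td <- withr::local_tempdir()
  cfg <- sim_config(genome_length_per_chrom = 200000, n_chroms = 1,
                    n_pairs = 1000, gap_length = 2000, seed = 17)
  for (d in c("a", "b")) {
    ds <- simulate_genome(cfg)
    ds <- implant_events(ds)
    ds <- suppressMessages(simulate_read_pairs(ds))
    write_dataset(ds, file.path(td, d))
  }
  for (f in list.files(file.path(td, "a"))) {
    expect_identical(tools::md5sum(file.path(td, "a", f))[[1]],
                     tools::md5sum(file.path(td, "b", f))[[1]],
                     label = f)
  }
})
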