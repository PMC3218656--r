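# Shared fixtures, built in code at test time. Heavier datasets are cached
# per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small implanted dataset with reads: 2 x 2 Mb, one somatic deletion with
# 2-bp microhomology, one tandem duplication, one deletion with an insert
tiny_dataset <- function() {
  cached("tiny", {
    cfg <- sim_config(genome_length_per_chrom = 2e6, n_chroms = 2,
                      n_pairs = 60000, gap_length = 5000, seed = 11)
    ds <- simulate_genome(cfg)
    ev <- rbind(
      truth_event("deletion", "chr1", 900001, 920000, microhomology = 2L,
                  homozygous = TRUE),
      truth_event("tandem_duplication", "chr1", 1400001, 1430000,
                  homozygous = TRUE),
      truth_event("deletion", "chr2", 500001, 514000, non_templated = "TTAA",
                  homozygous = TRUE),
      truth_event("inversion", "chr2", 900001, 950000, homozygous = TRUE))
    ds <- implant_events(ds, ev)
    suppressMessages(simulate_read_pairs(ds))
  })
}

make_pair <- function(chrom1 = "chr1", pos1, strand1 = "+", chrom2 = chrom1,
                      pos2, strand2 = "-", mapq1 = 60L, mapq2 = 60L,
                      alt_mapq = 60L, read_name = "r") {
  data.table::data.table(read_name = read_name, chrom1 = chrom1,
                         pos1 = as.integer(pos1), strand1 = strand1,
                         mapq1 = mapq1, chrom2 = chrom2,
                         pos2 = as.integer(pos2), strand2 = strand2,
                         mapq2 = mapq2, alt_mapq = alt_mapq)
}

make_pairs <- function(...) data.table::rbindlist(list(...))

# brute-force duplicate finder: connected components of the +/-1 bp
# relation by all-pairs comparison, keep max quality (ties: smallest name)
oracle_duplicates <- function(records, window = 1L) {
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- records$chrom1[i] == records$chrom1[j] &&
      records$chrom2[i] == records$chrom2[j] &&
      records$strand1[i] == records$strand1[j] &&
      records$strand2[i] == records$strand2[j] &&
      abs(records$pos1[i] - records$pos1[j]) <= window &&
      abs(records$pos2[i] - records$pos2[j]) <= window
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  keep <- vapply(unique(comp), function(cc) {
    g <- which(comp == cc)
    q <- records$mapq1[g] + records$mapq2[g]
    g <- g[q == max(q)]
    g[order(records$read_name[g])][1L]
  }, 0L)
  sort(records$read_name[keep])
}

# independent junction-scoring oracle: scans split points explicitly
oracle_score_junction <- function(junction, flank_a, flank_b) {
  J <- nchar(junction)
  left_max <- 0L
  for (p in seq_len(min(J, nchar(flank_a)))) {
    if (substr(junction, 1, p) == substr(flank_a, 1, p)) left_max <- p else break
  }
  right_max <- 0L
  for (p in seq_len(min(J, nchar(flank_b)))) {
    if (substr(junction, J - p + 1L, J) ==
        substr(flank_b, nchar(flank_b) - p + 1L, nchar(flank_b)))
      right_max <- p else break
  }
  if (left_max + right_max >= J)
    list(mh = left_max + right_max - J, nt = "")
  else list(mh = 0L, nt = substr(junction, left_max + 1L, J - right_max))
}

# toy gene pair on a toy genome for fusion frame tests; returns genome
# string + models with CDS spanning whole exons (minus small UTR trims)
toy_gene_genome <- function(seed = 1L, n_exons_a = 8L, n_exons_b = 8L) {
  set.seed(seed)
  glen <- 60000L
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  mk <- function(id, offset, n_ex) {
    ex_w <- sample(seq(99L, 300L, by = 3L), n_ex, replace = TRUE) +
      sample(0:2, n_ex, replace = TRUE)
    in_w <- sample(500:1500, n_ex - 1L, replace = TRUE)
    make_gene_model(id, "toy", "+",
                    exon_starts = offset + cumsum(c(0L, head(ex_w, -1L) + in_w)),
                    exon_widths = ex_w, cds_from = 1L, cds_to = n_ex)
  }
  a <- mk("geneA", 2000L, n_exons_a)
  b <- mk("geneB", 32000L, n_exons_b)
  list(genome = genome, models = rbind(a, b), a = a, b = b)
}

spliced_cds <- function(genome, g, exons) {
  g <- g[order(g$exon_number), ]
  sel <- g[g$exon_number %in% exons & !is.na(g$cds_start), , drop = FALSE]
  paste(vapply(seq_len(nrow(sel)), function(i)
    substr(genome, sel$cds_start[i], sel$cds_end[i]), ""), collapse = "")
}

translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1, n)),
                                     if.fuzzy.codon = "X"))
}

# translation oracle: a fusion/deletion transcript is in frame iff the
# protein tail downstream of the junction equals the acceptor's native tail
oracle_fusion_in_frame <- function(genome, don, acc, five_exon, three_exon,
                                   k = 6L) {
  fused <- paste0(spliced_cds(genome, don, seq_len(five_exon)),
                  spliced_cds(genome, acc, seq(three_exon, max(acc$exon_number))))
  native <- spliced_cds(genome, acc, seq_len(max(acc$exon_number)))
  pf <- translate_dna(fused); pn <- translate_dna(native)
  if (nchar(pf) < k || nchar(pn) < k) return(NA)
  substr(pf, nchar(pf) - k + 1L, nchar(pf)) ==
    substr(pn, nchar(pn) - k + 1L, nchar(pn))
}

oracle_deletion_in_frame <- function(genome, g, deleted, k = 6L) {
  keep <- setdiff(seq_len(max(g$exon_number)), deleted)
  modified <- spliced_cds(genome, g, keep)
  native <- spliced_cds(genome, g, seq_len(max(g$exon_number)))
  pm <- translate_dna(modified); pn <- translate_dna(native)
  substr(pm, nchar(pm) - k + 1L, nchar(pm)) ==
    substr(pn, nchar(pn) - k + 1L, nchar(pn))
}

# planted LRP1B-like cohort: 58-exon gene, internal exon widths 100 bp
# (each = 1 mod 3, so a run of r deleted exons is in frame iff r %% 3 == 0)
lrp1b_cohort <- function(n_samples = 770L, seed = 5L) {
  set.seed(seed)
  n_ex <- 58L
  gene <- make_gene_model("LRP1B", "chr2", "+",
                          exon_starts = 100000L + (seq_len(n_ex) - 1L) * 2000L,
                          exon_widths = rep(100L, n_ex),
                          cds_from = 1L, cds_to = n_ex)
  inframe_runs <- c(rep(3L, 10L), rep(6L, 7L), rep(9L, 3L))    # 20 samples
  offframe_runs <- c(rep(2L, 6L), rep(4L, 4L), rep(7L, 2L))    # 12 samples
  runs <- c(inframe_runs, offframe_runs)
  profs <- list(); truth <- list()
  for (i in seq_along(runs)) {
    first <- sample(2:(n_ex - 1L - runs[i]), 1L)
    ex <- gene[gene$exon_number %in% c(first, first + runs[i] - 1L), ]
    s <- min(ex$start) - 50L; e <- max(ex$end) + 50L
    sid <- sprintf("CL%03d", i)
    profs[[i]] <- data.frame(sample_id = sid, chrom = "chr2",
                             start = c(1L, s, e + 1L),
                             end = c(s - 1L, e, 400000L),
                             cn = c(2L, 0L, 2L))
    truth[[i]] <- data.frame(sample_id = sid, first = first,
                             run = runs[i], in_frame = runs[i] %% 3L == 0L)
  }
  # one deletion confined to an intron: internal HD, no exon removed
  s <- gene$end[gene$exon_number == 10L] + 200L
  profs[[33L]] <- data.frame(sample_id = "CL033", chrom = "chr2",
                             start = c(1L, s, s + 1000L),
                             end = c(s - 1L, s + 999L, 400000L),
                             cn = c(2L, 0L, 2L))
  # the rest of the cohort: clean diploid (some with CN 1 dips elsewhere)
  for (i in 34:n_samples) {
    profs[[i]] <- data.frame(sample_id = sprintf("CL%03d", i), chrom = "chr2",
                             start = 1L, end = 400000L,
                             cn = sample(c(1L, 2L, 3L), 1L))
  }
  list(gene = gene,
       profile = do.call(rbind, c(profs, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
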