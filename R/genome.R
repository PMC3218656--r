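#' Simulate a reference genome with masks and gene models
#'
#' Builds a small multi-chromosome reference of uniform random sequence,
#' together with the interval masks the downstream filters need (a
#' SINE/LTR-like repeat mask, a terminal assembly-gap interval at each
#' chromosome end, and a set of germline deletions recorded as truth events
#' but not yet applied to any sequence), and multi-exon gene models with
#' coding phases. Deterministic for a given seed.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `config`, `reference` (named character vector of chromosome sequences),
#'   `masks` (list of data.frames `repeats`, `gaps`, `germline_sv`),
#'   `gene_models` (exon-level data.frame), and `truth` (event data.frame,
#'   germline rows only at this stage). Tumor/normal genomes and read pairs
#'   are added by [implant_events()] and [simulate_read_pairs()].
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  L <- config$genome_length_per_chrom
  chroms <- paste0("chr", seq_len(config$n_chroms))

  if (config$gap_length * 2L >= L)
    stop("genome too short: terminal gaps would cover whole chromosomes")

  reference <- setNames(vapply(chroms, function(ch) random_dna(L), ""), chroms)

  gaps <- data.frame(
    chrom = rep(chroms, each = 2L),
    start = rep(c(1L, L - config$gap_length + 1L), times = length(chroms)),
    end   = rep(c(config$gap_length, L), times = length(chroms)),
    stringsAsFactors = FALSE
  )

  repeats <- simulate_repeat_mask(chroms, L, config$repeat_fraction)

  gene_models <- simulate_gene_models(chroms, L, repeats, gaps,
                                      n_genes = config$n_genes)

  truth <- empty_truth()
  germline <- list()
  if (config$n_germline_sv > 0L) {
    for (i in seq_len(config$n_germline_sv)) {
      ch <- chroms[(i - 1L) %% length(chroms) + 1L]
      size <- sample(2000:5000, 1L)
      start <- pick_clear_position(L, size, repeats, gaps, gene_models, ch)
      germline[[i]] <- truth_event("deletion", ch, start, start + size - 1L,
                                   somatic = FALSE, homozygous = TRUE)
    }
    truth <- do.call(rbind, germline)
  }
  germline_sv <- if (nrow(truth)) {
    data.frame(chrom = truth$chrom1, start = truth$pos1, end = truth$pos2,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }

  structure(list(
    config = config,
    reference = reference,
    masks = list(repeats = repeats, gaps = gaps, germline_sv = germline_sv),
    gene_models = gene_models,
    truth = truth,
    tumor_genome = NULL,
    normal_genome = NULL,
    tumor_pairs = NULL,
    normal_pairs = NULL
  ), class = "synthetic_dataset")
}

# Repeat intervals: mixture of short SINE-like (~150-300 bp) and long
# LTR-like (~2-6 kb) elements, placed uniformly until the target fraction of
# each chromosome is covered. Intervals may touch but reduce() keeps the
# mask tidy.
simulate_repeat_mask <- function(chroms, L, fraction) {
  out <- list()
  for (ch in chroms) {
    if (fraction <= 0) next
    target <- fraction * L
    covered <- 0
    starts <- integer(); ends <- integer()
    while (covered < target) {
      w <- if (runif(1) < 0.8) sample(150:300, 1L) else sample(2000:6000, 1L)
      s <- sample.int(L - w, 1L)
      starts <- c(starts, s); ends <- c(ends, s + w - 1L)
      covered <- covered + w
    }
    ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
    out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(ir),
                            end = IRanges::end(ir), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

simulate_gene_models <- function(chroms, L, repeats, gaps, n_genes) {
  models <- list()
  gid <- 0L
  if (n_genes < 1L)
    return(make_gene_model("none", chroms[1L], "+", 1L, 1L, NULL)[0L, ])
  for (ch in chroms) {
    for (g in seq_len(n_genes)) {
      gid <- gid + 1L
      n_ex <- sample(4:10, 1L)
      ex_w <- sample(100:300, n_ex, replace = TRUE)
      in_w <- sample(500:5000, n_ex - 1L, replace = TRUE)
      glen <- sum(ex_w) + sum(in_w)
      gstart <- pick_clear_position(L, glen, repeats, gaps, NULL, ch)
      strand <- sample(c("+", "-"), 1L)
      models[[gid]] <- make_gene_model(
        gene_id = sprintf("gene%03d", gid), chrom = ch, strand = strand,
        exon_starts = gstart + cumsum(c(0L, head(ex_w, -1L) + in_w)),
        exon_widths = ex_w,
        cds_from = 2L, cds_to = n_ex - 1L
      )
    }
  }
  do.call(rbind, c(models, list(make.row.names = FALSE)))
}

# uniformly pick a start so [start, start+size-1] avoids masks/genes,
# with a 1-kb margin; errors out when the genome cannot host the feature
pick_clear_position <- function(L, size, repeats, gaps, gene_models, ch,
                                margin = 1000L, tries = 200L) {
  occupied <- rbind(
    if (!is.null(repeats) && nrow(repeats)) repeats[repeats$chrom == ch, c("start", "end")],
    if (!is.null(gaps) && nrow(gaps)) gaps[gaps$chrom == ch, c("start", "end")],
    if (!is.null(gene_models) && nrow(gene_models)) {
      gm <- gene_models[gene_models$chrom == ch, , drop = FALSE]
      if (nrow(gm)) data.frame(start = min(gm$start), end = max(gm$end)) else NULL
    }
  )
  occ <- if (is.null(occupied) || nrow(occupied) == 0L)
    IRanges::IRanges() else IRanges::IRanges(occupied$start, occupied$end)
  for (t in seq_len(tries)) {
    s <- sample.int(max(1L, L - size - margin), 1L)
    q <- IRanges::IRanges(max(1L, s - margin), s + size - 1L + margin)
    if (!any(IRanges::overlapsAny(q, occ))) return(s)
  }
  stop(sprintf("genome too short to place a %d-bp feature on %s", size, ch))
}

#' Construct an exon-level gene model
#'
#' Exons are given in genomic order; exon numbering is 1-based in
#' transcription order (reversed for minus-strand genes). The CDS spans
#' exons `cds_from` to `cds_to` (transcription order), trimmed by small UTR
#' offsets so the coding length is a multiple of 3 plus a stop. The `phase`
#' column stores the cumulative coding length upstream of each exon mod 3
#' (0 for non-coding exons).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param exon_starts,exon_widths genomic starts and widths, ascending.
#' @param cds_from,cds_to first/last coding exon in transcription order;
#'   `NULL` for a non-coding gene.
#' @return exon-level data.frame, one row per exon.
#' @export
make_gene_model <- function(gene_id, chrom, strand, exon_starts, exon_widths,
                            cds_from = 1L, cds_to = length(exon_starts)) {
  n <- length(exon_starts)
  stopifnot(length(exon_widths) == n, n >= 1L, strand %in% c("+", "-"))
  start <- as.integer(exon_starts)
  end <- start + as.integer(exon_widths) - 1L
  if (is.unsorted(start)) stop("exon_starts must be ascending")
  if (any(head(end, -1L) >= tail(start, -1L))) stop("exons must not overlap")
  exon_number <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   exon_number = exon_number, start = start, end = end,
                   cds_start = NA_integer_, cds_end = NA_integer_,
                   phase = NA_integer_, stringsAsFactors = FALSE)
  df <- df[order(df$exon_number), ]
  if (!is.null(cds_from)) {
    stopifnot(cds_from >= 1L, cds_to <= n, cds_from <= cds_to)
    for (k in seq_len(n)) {
      i <- which(df$exon_number == k)
      if (k < cds_from || k > cds_to) next
      s <- df$start[i]; e <- df$end[i]
      if (k == cds_from) { # trim a 10-bp-ish 5' UTR inside the first coding exon
        utr <- min(10L, df$end[i] - df$start[i])
        if (strand == "+") s <- s + utr else e <- e - utr
      }
      if (k == cds_to) {
        utr <- min(10L, df$end[i] - df$start[i])
        if (strand == "+") e <- e - utr else s <- s + utr
      }
      df$cds_start[i] <- s; df$cds_end[i] <- e
    }
    # phases: cumulative coding length upstream of each exon, mod 3
    cum <- 0L
    for (k in seq_len(n)) {
      i <- which(df$exon_number == k)
      if (!is.na(df$cds_start[i])) {
        df$phase[i] <- cum %% 3L
        cum <- cum + (df$cds_end[i] - df$cds_start[i] + 1L)
      }
    }
  }
  rownames(df) <- NULL
  df
}
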