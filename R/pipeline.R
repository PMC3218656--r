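#' Run the full somatic rearrangement pipeline on a synthetic dataset
#'
#' Orchestrates the analysis sequence: filter tumor and normal pairs,
#' build mappable bins and count qualifying pairs, segment copy number,
#' cluster and call rearrangements with normal subtraction, score truth
#' junctions, and predict transcript effects for calls matched to truth
#' breakends (base-resolution breakends come from the simulator, standing
#' in for the capillary sequencing of the original protocol).
#'
#' @param dataset implanted `synthetic_dataset` with simulated pairs.
#' @param config a [pipeline_config()].
#' @param outdir optional run directory; when given, every stage output and
#'   a reproducibility manifest are written there.
#' @return list with `filtered_tumor`, `filtered_normal`, `bins`,
#'   `segments`, `calls`, `signatures`, `histogram`, `effects`, `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), outdir = NULL) {
  stopifnot(!is.null(dataset$tumor_pairs))
  ft <- filter_pairs(dataset$tumor_pairs, dataset$masks, config)
  fn <- filter_pairs(dataset$normal_pairs, dataset$masks, config)

  bins <- build_mappable_bins(dataset$reference, dataset$masks$repeats,
                              dataset$masks$gaps, target = config$bin_target)
  bins <- count_pairs_in_bins(ft$concordant, bins,
                              min_alt_quality = config$min_alt_quality,
                              concordant_span_max = config$concordant_span_max)
  segments <- segment_copy_number(bins, alpha = config$cbs_alpha,
                                  n_permutations = config$cbs_permutations,
                                  seed = config$seed,
                                  min_width = config$cbs_min_width)

  calls <- call_rearrangements(ft$discordant, segments, config,
                               normal_discordant = fn$discordant,
                               sample = "tumor")

  signatures <- NULL; histogram <- NULL
  if (nrow(dataset$truth)) {
    signatures <- score_truth_junctions(dataset, width = config$flank_width)
    signatures$genotype <- "synthetic"
    amp <- flag_amplicon_association(
      data.table::data.table(chrom1 = dataset$truth$chrom1,
                             be1 = dataset$truth$pos1,
                             chrom2 = dataset$truth$chrom2,
                             be2 = dataset$truth$pos2),
      segments, config$amplification_threshold)
    signatures$amplicon_associated <- amp$amplicon_associated
    histogram <- aggregate_signatures(signatures)
  }

  effects <- predict_effects_for_calls(calls, dataset$truth,
                                       dataset$gene_models,
                                       window = config$cluster_window)

  manifest <- build_manifest(dataset, config, ft, fn, bins, segments, calls)
  res <- list(filtered_tumor = ft, filtered_normal = fn, bins = bins,
              segments = segments, calls = calls, signatures = signatures,
              histogram = histogram, effects = effects, manifest = manifest)
  if (!is.null(outdir)) write_run(res, dataset, outdir)
  res
}

#' Match calls to truth events by geometry
#'
#' A call matches a truth event when chromosomes and strand patterns agree
#' and both breakends lie within `window` bp of the truth breakends.
#'
#' @param calls calls data.table with `be1`/`be2`.
#' @param truth truth event data.frame.
#' @param window matching window in bp.
#' @return integer vector: row index into `truth` per call (NA = unmatched).
#' @export
match_calls_to_truth <- function(calls, truth, window = 1000L) {
  vapply(seq_len(nrow(calls)), function(i) {
    cc <- calls[i, ]
    hit <- which(truth$chrom1 == cc$chrom1 & truth$chrom2 == cc$chrom2 &
                   truth$strand1 == cc$strand1 & truth$strand2 == cc$strand2 &
                   abs(truth$pos1 - cc$be1) <= window &
                   abs(truth$pos2 - cc$be2) <= window)
    if (length(hit)) hit[1L] else NA_integer_
  }, 0L)
}

predict_effects_for_calls <- function(calls, truth, gene_models,
                                      window = 1000L) {
  if (is.null(calls) || nrow(calls) == 0L)
    return(effect_row(character(0), character(0))[0, ])
  idx <- match_calls_to_truth(calls, truth, window)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    if (!is.na(idx[i])) {
      tv <- truth[idx[i], ]
      cl <- list(event_id = tv$event_id, chrom1 = tv$chrom1, pos1 = tv$pos1,
                 strand1 = tv$strand1, chrom2 = tv$chrom2, pos2 = tv$pos2,
                 strand2 = tv$strand2)
    } else {
      cc <- calls[i, ]
      cl <- list(event_id = sprintf("call%03d", i), chrom1 = cc$chrom1,
                 pos1 = cc$be1, strand1 = cc$strand1, chrom2 = cc$chrom2,
                 pos2 = cc$be2, strand2 = cc$strand2)
    }
    predict_effect(cl, gene_models)
  })
  do.call(rbind, rows)
}

build_manifest <- function(dataset, config, ft, fn, bins, segments, calls) {
  list(
    package_version = as.character(utils::packageVersion("somaticSV")),
    sim_config = unclass(dataset$config),
    pipeline_config = unclass(config),
    seed_trail = list(
      master = dataset$config$seed,
      genome = derive_seed(dataset$config$seed, "genome"),
      reads = derive_seed(dataset$config$seed, "reads"),
      cbs = derive_seed(config$seed, "cbs")),
    counts = list(
      tumor_pairs_in = nrow(dataset$tumor_pairs),
      normal_pairs_in = nrow(dataset$normal_pairs),
      tumor_removed = ft$counts,
      normal_removed = fn$counts,
      tumor_retained_concordant = nrow(ft$concordant),
      tumor_retained_discordant = nrow(ft$discordant),
      n_bins = nrow(bins),
      n_segments = nrow(segments),
      n_calls = if (is.null(calls)) 0L else nrow(calls)),
    physical_coverage = dataset$read_log$physical_coverage %||% NA
  )
}

#' Write a simulated dataset to a directory in standard formats
#'
#' Reference FASTA, per-class mask BEDs, gene models as GTF, truth as
#' BEDPE + TSV, and both samples' pairs as TSV and coordinate-sorted SAM.
#'
#' @param dataset implanted `synthetic_dataset` with pairs.
#' @param outdir output directory (created).
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$reference, file.path(outdir, "reference.fa"))
  write_bed(dataset$masks$repeats, file.path(outdir, "repeats.bed"))
  write_bed(dataset$masks$gaps, file.path(outdir, "gaps.bed"))
  write_bed(dataset$masks$germline_sv, file.path(outdir, "germline_sv.bed"))
  write_gtf(dataset$gene_models, file.path(outdir, "genes.gtf"))
  write_bedpe(dataset$truth, file.path(outdir, "truth.bedpe"))
  write_tsv(dataset$truth, file.path(outdir, "truth.tsv"),
            comment = "truth events; 1-based inclusive coordinates")
  lens <- nchar(dataset$reference)
  for (s in c("tumor", "normal")) {
    p <- dataset[[paste0(s, "_pairs")]]
    write_pairs_tsv(p, file.path(outdir, paste0(s, "_pairs.tsv")))
    write_sam(p, lens, file.path(outdir, paste0(s, ".sam")),
              read_length = dataset$config$read_length)
  }
  invisible(outdir)
}

write_run <- function(res, dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$filtered_tumor$outcomes,
            file.path(outdir, "tumor_filter_outcomes.tsv"),
            comment = "filter cascade outcomes; 1-based coordinates")
  removal <- data.frame(reason = names(res$filtered_tumor$counts),
                        n = unlist(res$filtered_tumor$counts))
  write_tsv(removal, file.path(outdir, "tumor_removals.tsv"))
  write_tsv(res$bins, file.path(outdir, "bins.tsv"),
            comment = "mappable bins; 1-based inclusive")
  write_tsv(res$segments, file.path(outdir, "segments.tsv"),
            comment = "copy-number segments; 1-based inclusive")
  if (!is.null(res$calls) && nrow(res$calls)) {
    write_bedpe(res$calls, file.path(outdir, "calls.bedpe"))
    af3 <- data.frame(
      Sample = res$calls$sample, `No.Reads` = res$calls$n_pairs,
      SimplifiedNomenclature = res$calls$event_type,
      Chr1 = res$calls$chrom1, Position1 = res$calls$be1,
      Strand1 = res$calls$strand1, Chr2 = res$calls$chrom2,
      Position2 = res$calls$be2, Strand2 = res$calls$strand2,
      Size = res$calls$span, ReadName = res$calls$read_name,
      check.names = FALSE)
    write_tsv(af3, file.path(outdir, "calls.tsv"),
              comment = "rearrangement calls; 1-based positions")
    type_counts <- as.data.frame(table(res$calls$event_type),
                                 stringsAsFactors = FALSE)
    names(type_counts) <- c("type", "count")
    write_tsv(type_counts, file.path(outdir, "call_type_counts.tsv"))
  }
  if (!is.null(res$signatures))
    write_tsv(res$signatures, file.path(outdir, "junction_signatures.tsv"))
  if (!is.null(res$histogram))
    write_tsv(res$histogram, file.path(outdir, "junction_histogram.tsv"))
  if (!is.null(res$effects) && nrow(res$effects))
    write_tsv(res$effects, file.path(outdir, "effects.tsv"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
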