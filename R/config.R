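#' Simulation configuration
#'
#' Describes the sequencing design the simulator emulates: a short-insert
#' paired-end library of 37-bp reads from fragments gel-selected to
#' 400-550 bp (mode around 450 bp), with a configurable amount of PCR
#' duplication, short-inverted-pair library artifacts and mismapping.
#'
#' @param genome_length_per_chrom chromosome length in bp.
#' @param n_chroms number of chromosomes.
#' @param read_length read length in bp.
#' @param fragment_size_min,fragment_size_mode,fragment_size_max fragment
#'   (insert) size distribution bounds and mode in bp; sizes are drawn from a
#'   triangular distribution, a simple bounded unimodal stand-in for a gel cut.
#' @param n_pairs number of genuine (non-duplicate, non-artifact) fragments
#'   to simulate per sample.
#' @param duplicate_rate fraction of extra pairs injected as PCR duplicates
#'   (both ends within 1 bp of an existing pair).
#' @param artifact_inverted_pair_rate fraction of extra pairs injected as
#'   short wrong-orientation singleton artifacts (span < 500 bp).
#' @param mismap_rate fraction of pairs given random coordinates and a low
#'   alternative mapping quality, emulating mapping error in repeats.
#' @param repeat_fraction approximate fraction of each chromosome covered by
#'   the simulated repeat mask (LTR/SINE-like intervals).
#' @param gap_length length in bp of the terminal assembly-gap interval
#'   placed at each chromosome end.
#' @param n_genes number of multi-exon gene models simulated per chromosome.
#' @param n_germline_sv number of germline deletions implanted in both the
#'   tumor and the matched normal genome.
#' @param seed master random seed; all stage seeds derive from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length_per_chrom = 1e6,
                       n_chroms = 2L,
                       read_length = 37L,
                       fragment_size_min = 400L,
                       fragment_size_mode = 450L,
                       fragment_size_max = 550L,
                       n_pairs = 20000L,
                       duplicate_rate = 0.05,
                       artifact_inverted_pair_rate = 0.01,
                       mismap_rate = 0.01,
                       repeat_fraction = 0.05,
                       gap_length = 10000L,
                       n_genes = 4L,
                       n_germline_sv = 1L,
                       seed = 1L) {
  cfg <- list(
    genome_length_per_chrom = as.integer(genome_length_per_chrom),
    n_chroms = as.integer(n_chroms),
    read_length = as.integer(read_length),
    fragment_size_min = as.integer(fragment_size_min),
    fragment_size_mode = as.integer(fragment_size_mode),
    fragment_size_max = as.integer(fragment_size_max),
    n_pairs = as.integer(n_pairs),
    duplicate_rate = duplicate_rate,
    artifact_inverted_pair_rate = artifact_inverted_pair_rate,
    mismap_rate = mismap_rate,
    repeat_fraction = repeat_fraction,
    gap_length = as.integer(gap_length),
    n_genes = as.integer(n_genes),
    n_germline_sv = as.integer(n_germline_sv),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(fragment_size_min <= fragment_size_mode &&
          fragment_size_mode <= fragment_size_max))
      stop("fragment sizes must satisfy min <= mode <= max")
    if (read_length >= fragment_size_min)
      stop("read_length must be smaller than fragment_size_min")
    rates <- c(duplicate_rate, artifact_inverted_pair_rate, mismap_rate,
               repeat_fraction)
    if (any(rates < 0 | rates > 1))
      stop("all rates must lie in [0, 1]")
    if (genome_length_per_chrom < 10 * fragment_size_max)
      stop("genome too short for the requested fragment sizes")
  })
  invisible(cfg)
}

#' Pipeline configuration
#'
#' Holds every numeric threshold of the analysis. Defaults reproduce the
#' published filtering and calling rules: concordant pairs map inward within
#' 600 bp; PCR duplicates are pairs with both ends within 1 bp; pairs within
#' 1 Mb of an assembly gap or with both ends within 500 bp of a germline
#' structural variant are removed; calling criteria use a 10-kb span, >= 2
#' independent pairs, alternative mapping quality >= 35 and a 100-kb
#' change-point window; copy-number bins target 15 kb of mappable sequence.
#'
#' @param min_span_criterion1 minimum span (bp) for the primary read-support
#'   criterion.
#' @param min_independent_pairs minimum number of read pairs with distinct
#'   end-position tuples.
#' @param min_alt_quality alternative-mapping-quality floor; at least one
#'   pair in a cluster must reach it, and only pairs at or above it count
#'   toward copy-number bins.
#' @param change_point_window bp window around a copy-number change point
#'   used by the copy-number-supported criteria.
#' @param concordant_span_max maximum span (bp) of a concordant pair.
#' @param duplicate_window bp tolerance when matching PCR-duplicate ends.
#' @param gap_exclusion bp exclusion distance around assembly gaps.
#' @param germline_proximity bp distance to a germline SV breakend within
#'   which both ends of a pair must lie for the pair to be removed.
#' @param inverted_artifact_span span (bp) below which a wrong-orientation
#'   singleton pair is treated as a library artifact.
#' @param flank_width flank width (bp) used for junction scoring; 10 or 100.
#' @param bin_target target mappable bp per copy-number bin.
#' @param cbs_alpha permutation p-value threshold for accepting a split.
#' @param cbs_permutations number of permutations per split test.
#' @param cbs_min_width minimum segment width in bins.
#' @param cluster_window bp window for co-clustering discordant pairs.
#' @param amplification_threshold fold-change over the genome median bin
#'   density above which a segment is amplicon-level.
#' @param min_low_confidence alternative-mapping-quality floor below which a
#'   pair is removed outright (0 = filter off).
#' @param enable_criterion4 logical; the 600 bp - 10 kb read-support-only
#'   criterion is manual curation in the original analysis and off by default.
#' @param subtract_normal logical; drop candidate somatic calls whose cluster
#'   is supported by at least one pair in the matched normal.
#' @param seed master seed for the stochastic stages (segmentation
#'   permutations).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_span_criterion1 = 10000L,
                            min_independent_pairs = 2L,
                            min_alt_quality = 35L,
                            change_point_window = 100000L,
                            concordant_span_max = 600L,
                            duplicate_window = 1L,
                            gap_exclusion = 1000000L,
                            germline_proximity = 500L,
                            inverted_artifact_span = 500L,
                            flank_width = 10L,
                            bin_target = 15000L,
                            cbs_alpha = 0.01,
                            cbs_permutations = 1000L,
                            cbs_min_width = 3L,
                            cluster_window = 1000L,
                            amplification_threshold = 5,
                            min_low_confidence = 0L,
                            enable_criterion4 = FALSE,
                            subtract_normal = TRUE,
                            seed = 1L) {
  cfg <- list(
    min_span_criterion1 = as.integer(min_span_criterion1),
    min_independent_pairs = as.integer(min_independent_pairs),
    min_alt_quality = as.integer(min_alt_quality),
    change_point_window = as.integer(change_point_window),
    concordant_span_max = as.integer(concordant_span_max),
    duplicate_window = as.integer(duplicate_window),
    gap_exclusion = as.integer(gap_exclusion),
    germline_proximity = as.integer(germline_proximity),
    inverted_artifact_span = as.integer(inverted_artifact_span),
    flank_width = as.integer(flank_width),
    bin_target = as.integer(bin_target),
    cbs_alpha = cbs_alpha,
    cbs_permutations = as.integer(cbs_permutations),
    cbs_min_width = as.integer(cbs_min_width),
    cluster_window = as.integer(cluster_window),
    amplification_threshold = amplification_threshold,
    min_low_confidence = as.integer(min_low_confidence),
    enable_criterion4 = isTRUE(enable_criterion4),
    subtract_normal = isTRUE(subtract_normal),
    seed = as.integer(seed)
  )
  dists <- c(cfg$min_span_criterion1, cfg$change_point_window,
             cfg$concordant_span_max, cfg$gap_exclusion,
             cfg$germline_proximity, cfg$bin_target, cfg$cluster_window)
  if (any(dists <= 0)) stop("all distance parameters must be positive")
  if (!cfg$flank_width %in% c(10L, 100L))
    stop("flank_width must be 10 or 100")
  structure(cfg, class = "pipeline_config")
}
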