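#' Call homozygously deleted exons from an integer copy-number profile
#'
#' Adjacent copy-number-zero segments are merged into contiguous CN=0
#' regions first (segment boundaries are artifacts of upstream
#' segmentation); an exon is called homozygously deleted iff it lies
#' entirely within such a region (strict containment — partial overlap
#' does not delete an exon). A call is `internal` when the deleted exon set
#' is a non-empty proper subset of the gene's exons excluding the first and
#' the last (transcription order); CN=0 across every exon is a whole-gene
#' deletion. Genes with no deleted exon are not emitted.
#'
#' @param profile data.frame (`sample_id`, `chrom`, `start`, `end`, `cn`),
#'   non-overlapping integer copy-number segments.
#' @param gene_models exon-level gene model data.frame.
#' @return data.frame of calls: `sample_id`, `gene_id`, `deleted_exons`
#'   (comma-separated), `n_deleted`, `internal`, `whole_gene`.
#' @export
call_homozygous_exon_deletions <- function(profile, gene_models) {
  stopifnot(all(profile$cn >= 0), all(profile$cn == floor(profile$cn)))
  out <- list()
  for (sid in unique(profile$sample_id)) {
    p <- profile[profile$sample_id == sid & profile$cn == 0, , drop = FALSE]
    zero <- if (nrow(p)) {
      sp <- split(p, p$chrom)
      do.call(rbind, lapply(names(sp), function(ch) {
        # merge touching/adjacent CN=0 segments into contiguous regions
        ir <- IRanges::reduce(IRanges::IRanges(sp[[ch]]$start, sp[[ch]]$end),
                              min.gapwidth = 1L)
        data.frame(chrom = ch, start = IRanges::start(ir),
                   end = IRanges::end(ir), stringsAsFactors = FALSE)
      }))
    } else NULL
    if (is.null(zero) || nrow(zero) == 0L) next
    for (gid in unique(gene_models$gene_id)) {
      g <- gene_rows(gene_models, gid)
      z <- zero[zero$chrom == g$chrom[1L], , drop = FALSE]
      if (!nrow(z)) next
      del <- g$exon_number[vapply(seq_len(nrow(g)), function(i)
        any(g$start[i] >= z$start & g$end[i] <= z$end), TRUE)]
      if (!length(del)) next
      n_ex <- max(g$exon_number)
      whole <- length(del) == n_ex
      internal <- !whole && !(1L %in% del) && !(n_ex %in% del)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, gene_id = gid,
        deleted_exons = paste(sort(del), collapse = ","),
        n_deleted = length(del), internal = internal, whole_gene = whole,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene_id = character(),
                      deleted_exons = character(), n_deleted = integer(),
                      internal = logical(), whole_gene = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Would an in-frame transcript remain after an exon deletion?
#'
#' True iff the total deleted coding length is a multiple of 3; a deletion
#' touching only untranslated exons leaves the coding sequence intact and
#' is in frame by definition.
#'
#' @param call one row from [call_homozygous_exon_deletions()].
#' @param gene_model exon rows of the gene.
#' @return logical.
#' @export
frame_after_deletion <- function(call, gene_model) {
  del <- as.integer(strsplit(call$deleted_exons, ",", fixed = TRUE)[[1]])
  cds_width(gene_model, del) %% 3L == 0L
}

#' Summarize internal-deletion frequency over a cohort
#'
#' @param calls calls data.frame from [call_homozygous_exon_deletions()].
#' @param n_samples cohort size (>= 1).
#' @param digits decimals for the reported percentage.
#' @param mode "round" or "truncate" for the percentage display.
#' @return list: `n_with_internal_deletion`, `proportion` (exact),
#'   `percent` (formatted per `digits`/`mode`).
#' @export
summarize_cohort <- function(calls, n_samples, digits = 1L,
                             mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(n_samples >= 1L)
  n_int <- length(unique(calls$sample_id[calls$internal]))
  prop <- n_int / n_samples
  pct <- prop * 100
  pct_out <- if (mode == "round") round(pct, digits)
  else floor(pct * 10^digits) / 10^digits
  list(n_with_internal_deletion = n_int, proportion = prop,
       percent = pct_out)
}

#' Order deletion patterns by hierarchical clustering
#'
#' Optional report ordering: rows are per-sample binary exon-deletion
#' vectors, clustered with Euclidean distance and average linkage.
#'
#' @param calls calls data.frame (one gene).
#' @param n_exons number of exons in the gene.
#' @return character vector of sample_ids in dendrogram order.
#' @export
cluster_deletion_patterns <- function(calls, n_exons) {
  if (nrow(calls) < 3L) return(calls$sample_id)
  m <- t(vapply(seq_len(nrow(calls)), function(i) {
    v <- integer(n_exons)
    v[as.integer(strsplit(calls$deleted_exons[i], ",", fixed = TRUE)[[1]])] <- 1L
    v
  }, integer(n_exons)))
  rownames(m) <- calls$sample_id
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  calls$sample_id[hc$order]
}
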