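Package: somaticSV
Title: Somatic Structural Rearrangement Discovery from Paired-End Read Mappings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for calling somatic structural rearrangements
    in tumor/normal pairs sequenced with short-insert paired-end libraries.
    Discordantly mapped read pairs are filtered through a cascade of
    PCR-duplicate, repeat, assembly-gap, artifact and germline-variant
    filters, clustered into candidate rearrangements, and evaluated against
    read-support and copy-number-change criteria. Read-depth copy number is
    computed in mappable-sequence bins and segmented by circular binary
    segmentation. Base-pair-resolved junctions are classified by
    microhomology and non-templated sequence, rearrangements are intersected
    with gene models to predict in-frame fusion and internally deleted
    transcripts, and integer copy-number profiles are scanned for homozygous
    internal exon deletions. A synthetic-data module generates small
    tumor/normal genomes with implanted rearrangements of known truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Rcpp,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
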