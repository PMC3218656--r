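---
title: "Calling somatic structural rearrangements from short-insert paired-end libraries"
author: "somaticSV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic structural rearrangements from short-insert paired-end libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

somaticSV reimplements, as a tested pipeline, the classical paired-end
mapping approach to somatic structural variation in tumor/normal pairs:
37-bp read pairs from ~450-bp fragments are mapped to a reference; pairs
whose orientation, separation or chromosome assignment is inconsistent with
an intact fragment ("discordant" pairs) mark candidate rearrangements.
Because short-read mappings in a repeat-rich mammalian genome are noisy,
the discovery step is dominated by a carefully ordered exclusion cascade,
and candidate junctions are then interpreted through read-depth copy
number, junction sequence context, and gene models.

The package contains seven modules: a synthetic-data generator
(`simulate_genome()`, `implant_events()`, `simulate_read_pairs()`), the
pair-filtering cascade (`filter_pairs()`), binned read-depth copy number
with circular binary segmentation (`build_mappable_bins()`,
`count_pairs_in_bins()`, `segment_copy_number()`), discordant-pair
clustering and rearrangement calling (`call_rearrangements()`), breakpoint
microhomology analysis (`score_junction()`, `aggregate_signatures()`),
transcript-effect prediction (`predict_effect()`, `determine_frame()`), and
an exon-level homozygous-deletion scanner over integer copy-number profiles
(`call_homozygous_exon_deletions()`).

# The filtering model

Every threshold lives in `pipeline_config()` and defaults to the published
protocol values:

* concordant pairs map inward (`+` end leftmost) within **600 bp** — just
  above the 550-bp ceiling of the gel-selected insert distribution;
* **PCR duplicates**: both ends within ±1 bp (same chromosomes and
  strands); only the highest-total-mapping-quality pair of each group is
  kept. The ±1-bp relation is not transitive, so groups are its connected
  components (union-find); quality ties break on the lexicographically
  smallest read name, for determinism;
* **repeat mask**: any pair with an end inside an annotated repeat
  (LTR/SINE-class in the emulated genome) is removed;
* **assembly gaps**: any pair with an end within **1 Mb** of a gap interval
  is removed, measured from the interval's nearest edge;
* **inverted-singleton artifacts**: wrong-orientation pairs with both ends
  within **500 bp** are library artifacts unless a second independent pair
  supports the same junction (co-clusters under the calling module's rule);
* **germline proximity**: pairs with *both* ends within **500 bp** of a
  known germline SV breakend are removed. We read the rule literally as
  both-ends and as breakend distance (not whole-interval distance); the
  alternative readings would only remove more pairs near germline events,
  which the matched-normal subtraction already handles.

A configurable alternative-mapping-quality floor
(`min_low_confidence`, default 0 = off) stands in for the original
re-alignment-based rescue of ambiguous mappings: re-alignment itself is out
of scope, and the quality field carries its effect in both simulated and
real input.

# Copy number

The genome is divided into bins of approximately **15 kb of mappable
sequence**, where mappable is the complement of the repeat and gap masks (a
synthetic stand-in for a true mappability track). Bin genomic widths vary
accordingly. Concordant pairs with alternative mapping quality **>= 35**
are assigned to the bin containing the fragment midpoint — symmetric and
unambiguous for ~450-bp fragments against 15-kb bins.

Segmentation is recursive circular binary segmentation: within each
chromosome the arc of bins maximizing the standardized mean-difference
statistic is accepted as a split when its permutation p-value falls below
`alpha`, then the pieces are segmented recursively. The cited algorithm is
parameter-free in the source, so defaults were chosen once: `alpha = 0.01`,
1,000 permutations, minimum segment width 3 bins, and a square-root
variance-stabilizing transform for the Poisson-like counts (which also
makes the segmentation exactly invariant to rescaling all counts). The
inner maximization is compiled code; permutations use R's RNG, so results
are reproducible under a seed, and permutation runs stop early once the
exceedance count proves the p-value is above `alpha`. A constant signal
yields a single segment with no special casing.

# Calling criteria

Filtered discordant pairs co-cluster when they share a chromosome pair and
strand pattern and both ends lie within a **1-kb window** (the insert
ceiling plus roughly three times the insert spread; the source presumes a
grouping rule but does not state one). "Independent" support counts
distinct (pos1, pos2) tuples at **both** ends — the stricter of the two
possible readings. Clusters become calls under the lowest-numbered
criterion they satisfy:

1. ends >= 10 kb apart, >= 2 independent pairs, at least one with
   alternative quality >= 35;
2. ends >= 10 kb apart, a single qualifying pair with both ends within
   100 kb of a copy-number change point;
3. ends >= 600 bp apart, >= 2 independent pairs, both ends within 100 kb of
   a change point;
4. ends 600 bp-10 kb apart with >= 2 independent pairs — described as
   "selected" (manually curated) in the source protocol, so implemented
   behind `enable_criterion4 = FALSE`.

Interchromosomal clusters have no defined separation; they are treated as
satisfying the span condition (otherwise no interchromosomal event could
ever be reported, contradicting the source's own results). Event types
follow breakend geometry: long inward `+/-` = deletion, everted `-/+` =
tandem duplication, equal strands = inversion, different chromosomes =
interchromosomal. A call is amplification-associated when either breakend
falls in a segment at or above `amplification_threshold` (default 5) times
the genome median bin density; zero-density bins (gaps, homozygous losses)
are excluded from that baseline because on desk-scale genomes a single
large homozygous deletion would otherwise drag the median to zero.

Somatic status is established by in-silico subtraction: a candidate whose
cluster is supported by even one pair in the matched normal is dropped.
This replaces the tumor-versus-spleen PCR of the original protocol; it is a
methodological substitution, not a reimplementation.

# Junction signatures

Double-strand-break repair by non-homologous end joining or
microhomology-mediated repair leaves characteristic scars: short sequence
shared by both flanks (microhomology) or inserted bases matching neither
flank (non-templated sequence). Scoring anchors the sequenced junction to
the two reference flanks (10-bp or 100-bp windows on either side of each
breakpoint): with `L` the maximal left-anchored match, `R` the maximal
right-anchored match and `J` the junction length, `L + R - J > 0` is
microhomology of that length, `L + R = J` a blunt join, and a gap is the
non-templated insert. Microhomology requires exact matches — the source
defines no mismatch tolerance, and the exact definition keeps the two
classes mutually exclusive by construction. Where several split points are
equivalent (the inherent ambiguity of microhomology) the leftmost is
reported; lengths are unaffected. Junctions anchored by fewer than 3 bases
per side are excluded as unresolved, with a count.

"Shards" — small fragments shuffled into complex rearrangements — are
excluded from aggregation by a documented stand-in heuristic: any event
with a breakend within 2 kb of another event's breakend in the same sample
(`flag_shards()`); the source does not define the term operationally.

# Transcript effects and reading frame

A breakend with strand `+` retains sequence to its left, `-` to its right.
A gene transcribing *toward* the junction on its retained side donates its
5' exons; a gene transcribing *away* accepts at its 3' exons. A fusion
requires one donor and one acceptor (transcriptional collinearity after
applying the event geometry); same-strand juxtapositions that would produce
antisense fusions are reported as `none` with a reason code. Deletions
internal to one gene splice the flanking exons together; removing the first
or last exon is classified as truncation. Exon numbering is 1-based in
transcription order.

Frame status compares coding phase across the junction: in frame iff the
donor's retained coding length mod 3 equals the cumulative-phase of the
acceptor's first retained exon (equivalently, for internal deletions, the
deleted coding length is a multiple of 3). Two edge policies are
documented choices: a donor contributing only untranslated exons is in
frame iff the acceptor retains its own start codon (a single ORF then spans
the junction — the policy needed for fusions whose 5' partner contributes
only UTR); a coding donor spliced into acceptor UTR is out of frame. The
frame rule is validated against an independent translation oracle
(reconstruct the spliced fusion CDS, translate it, and compare the protein
tail with the acceptor's native tail) on randomized gene models.

# Exon-level homozygous deletions

Given integer absolute copy-number segments (the output format of SNP-array
copy-number callers; their inference is out of scope), adjacent CN=0
segments are merged — their boundaries are artifacts of upstream
segmentation — and an exon is called homozygously deleted only when it lies
*entirely* inside a merged CN=0 region (strict containment). A call is
"internal" when the deleted set is a non-empty proper subset excluding the
first and last exon; CN=0 over every exon is a whole-gene deletion. The
cohort summary reports the exact fraction plus a percentage under both
rounding and truncation, because a published "4.2%" for 33/770 (= 4.29%) is
reproducible only under truncation and the original convention is
unknowable.

# The synthetic world

The generator emulates the sequencing design of the study it mirrors:
37-bp paired ends from fragments drawn on [400, 550] bp with mode 450 (a
triangular distribution — any bounded unimodal shape is defensible for a
gel cut; triangular is the simplest), written as already-mapped pairs
(alignment is out of scope; the source consumed aligner output).
Coordinates inside the package are 1-based inclusive, the natural R/IRanges
convention; BED/BEDPE outputs are converted to 0-based half-open on write.

The tumor is two haplotypes: haplotype A carries all implanted events,
haplotype B only germline and homozygous somatic events; the matched normal
carries the germline events alone. Junction microhomology or non-templated
inserts are *forced* by editing the reference before any sequence is built,
so every implanted junction scores exactly the requested signature;
inversion junctions record their realized (random-flank) signature instead.
Mapping qualities follow a three-level model — unique placements 60,
repeat-overlapping placements below 35, mismapped pairs random with quality
below 35 — which exercises the >= 35 filter without modelling an aligner.
PCR duplicates (0-1 bp jitter, reduced quality), short inverted-pair
artifacts and mismaps are injected at configurable rates (defaults 5%, 1%,
1%: unstated in the source; typical of that library era). Reads that cross
a junction within the read itself are dropped with a logged count, standing
in for alignment failure at breakpoints.

What a green test therefore establishes: the geometric and combinatorial
logic of every stage on data whose truth is exact. What it does not
establish: behaviour under base-calling error, aligner-specific mapping
bias, micro-heterogeneity of real tumors, or contamination — none of which
the generator models.

Two worked-example generators pin the package to the published geometries:
`simulate_cre_ladder_tumor()` implants the 20/14/8/7-kb engineered-allele
deletion ladder (the 20- and 14-kb deletions are callable under criterion 1;
the 8- and 7-kb ones fall below the 10-kb design boundary and must not be
called), and `simulate_fusion_tumor()` implants a 200-kb tandem duplication
fusing exon 2 of a donor to exon 2 of an acceptor and an 8-Mb deletion
fusing exon 6 to exon 5 — both in frame by construction (201-bp exons keep
all junction phases equal). Both generators scrub the repeat mask within
2 kb of implanted breakpoints: the events they emulate were base-pair
validated and therefore live in mappable sequence, and a 10-Mb toy genome
gives repeat placement an unrealistically high chance of colliding with a
breakpoint. Example coverage defaults to 10x physical coverage — the same
order as the ~7.5x of the emulated study, chosen once so that expected
junction support comfortably exceeds the 2-pair criterion.

# Numerical and degenerate-input policies

* Physical coverage is fragment span per base (`n_pairs x mean fragment /
  genome length`), distinct from sequence coverage; the source's own two
  printed numbers for this quantity are not mutually consistent, so the
  simulator reports it but no fixed value is asserted.
* A chromosome with less than one bin of mappable sequence yields a single
  flagged undersized bin; a fully masked chromosome a flagged empty bin.
* Empty inputs (zero pairs, empty event lists, empty cohorts) return empty
  but well-formed outputs, never errors.
* Mask intervals on unknown chromosomes warn and are ignored.
* All stage seeds derive deterministically from one master seed and are
  recorded in the run manifest; identical config + seed reproduces outputs
  byte-identically.

# Known limitations

* Breakends are cluster-window resolution; base-resolution junctions come
  from the simulator truth (standing in for the capillary sequencing of the
  original protocol). There is no split-read refinement.
* Amplification nesting inside other events and combining intra- with
  inter-chromosomal events on one chromosome are rejected rather than
  modelled.
* Only annotated single-transcript gene models are considered; no novel
  splice-site prediction.
* An optional FASTQ emitter is deliberately absent: simulated output is
  already-mapped pairs, and an untested emitter would suggest aligner
  interoperability the package does not verify.
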