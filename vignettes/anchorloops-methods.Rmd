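---
title: "Methods: classifying repressive loop anchors and head-to-tail TAD boundary genes"
author: "anchorloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying repressive loop anchors and head-to-tail TAD boundary genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorloops)
```

## The analyses and their assumptions

`anchorloops` implements two related genome-wide analyses of chromatin
architecture around H3K27ac-independent p300 sites.

**Loop analysis.** p300 marks both classical enhancers (with H3K27ac) and
a minority of H3K27ac-free sites. The package defines a *p300-only peak*
as a p300 peak sharing no base with any H3K27ac peak after the H3K27ac
set is extended by ±1 kb (`derive_p300_only`). Both anchors of every
chromatin loop are then annotated: an anchor's display class is
`p300only` if it overlaps a p300-only peak, else `H3K27me3` if it
overlaps that mark, else its gene feature — `Promoter` (TSS ±1 kb),
`Terminator` (TES ±5 kb), `Genebody`, or `Intergenic` — decided by that
precedence over all genes intersecting the anchor. The unordered pair of
display classes is the loop's interaction category; the headline summary
is the fraction of loops anchored by a p300-only peak on one side and
H3K27me3 on the other (`mark_fraction`). The same classification is
applied to TAD boundary windows (boundary ±5 kb), treating each TAD's
(left, right) window pair as one interaction. Genes looped to p300-only
anchors are compared on the log2(TPM+1) scale between H3K27me3-marked and
unmarked partners (two-sided rank-sum test), and the qualifying loops are
summarized by aggregate peak analysis on VC_SQRT-balanced matrices.

**Boundary analysis.** Each boundary window of each TAD is assigned `P`
if it intersects any promoter window, else `T` for a terminator window,
else `G` for a gene body, giving per-TAD pair categories (PP, PT, PG,
...). A *head-to-tail* pair is detected when two same-strand genes occupy
one TAD's two boundaries with the upstream gene's terminator window on
one and the downstream gene's promoter window on the other, upstream
preceding downstream in transcription direction; for `+` pairs the
terminator must sit at the left boundary, for `-` pairs at the right.
Detected pairs can be intersected with a user-supplied oncogene list
(`oncogene_scan`), reporting the fraction of the list found upstream.
Boundary-gene expression is compared across PP/PG/PT categories with the
Kruskal-Wallis test, counting each gene once per (TAD, boundary)
occurrence.

Assumptions worth making explicit: all coordinates follow BED half-open
semantics at the file level (overlap requires a shared base; book-ended
intervals do not overlap); genes must carry strand, since TSS and TES are
undefined otherwise; loops and TADs are intra-chromosomal for all matrix
work; and annotation quality (which isoforms, which TSS) directly moves
the boundary censuses, so the gene model is an explicit input rather than
a baked-in choice.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `promoter_flank` | 1000 | bp | half-width of the TSS window |
| `terminator_flank` | 5000 | bp | half-width of the TES window |
| `boundary_flank` | 5000 | bp | half-width of a TAD boundary window |
| `h3k27ac_extend` | 1000 | bp | H3K27ac extension before p300 exclusion |
| `apa_resolution` | 25000 | bp | contact-matrix bin size |
| `apa_window` | 6 | bins | APA half-width (13×13 window) |
| `merge_slack` | one bin | bp | center-to-center tolerance in `merge_loops` |

These defaults are the canonical window sizes for this analysis; all are
overridable per call or through `pipeline_config()`, and every pipeline
run writes a resolved-config snapshot next to its outputs.

## The synthetic genome

`generate_dataset()` builds a toy genome whose statistical structure
matches the assumptions of every downstream stage, so the whole pipeline
can be validated without downloads. Defaults: two chromosomes of 10 Mb at
25 kb resolution; 60 TADs tiling each chromosome with bin-aligned
boundaries (minimum 8 bins ≈ 200 kb); 400 genes with log-uniform lengths
in [2 kb, 100 kb] (spanning the promoter/terminator window scales without
overwhelming the toy chromosomes), random strand, random exon structure,
and a second internal-promoter isoform for ~10% of background genes; 200
loops with bin-aligned 25 kb anchors separated by 60–200 bins.

Planted structure, recorded in a ground-truth object:

- a fraction `planted_fraction` (default 0.1) of loops are *repressive*:
  anchor 1 is centered on a standalone p300 peak (no H3K27ac within
  reach of the ±1 kb extension) and anchor 2 on an H3K27me3 peak covering
  the promoter of a gene planted at the bin center;
- an equal `active_fraction` of loops pair a p300-only anchor with an
  unmarked promoter, so the two-group expression comparison has a
  non-H3K27me3 arm — without them that comparison would be degenerate;
- 5 head-to-tail TADs (alternating strand), plus 5 promoter–promoter and
  8 promoter–genebody boundary TADs so the PP/PG/PT expression
  comparison has all three groups;
- expression is drawn as log2(TPM+1) ~ Normal(μ = 4, σ = 1), minus a
  deficit δ = 1 for genes whose promoter lies in a planted H3K27me3
  anchor, clamped at 0 and back-transformed (the clamp affects ~3·10⁻⁵ of
  the mass at these defaults).

With `collision_free = TRUE` (default) background placements are rejected
whenever they could blur recovery: background gene promoters/terminators
stay ≥12 kb from every TAD boundary, promoters stay out of loop-anchor
bins, background peaks stay ≥2 kb from anchor bins, and planted TADs are
never adjacent (with head-to-tail strands alternating so that plants two
TADs apart cannot chain into an accidental pair in the TAD between them).
Under these conditions recovery is exact by construction, which is what
the recovery tests assert: the planted fraction is recovered as exactly
10.00%, and exactly the 5 planted head-to-tail TADs are detected, also
after reflecting the genome and flipping strands.

Contact matrices follow
`E[C_ij] = N (1 + |i − j|)^(−α) · t^[same TAD] · e^[planted pixel]`
with independent Poisson counts mirrored to a symmetric integer matrix;
defaults α = 1, t = 1.5, e = 3, N = 2000. Two of these were set by a
design calculation rather than taste. The APA score divides the window
center by the lower-left 3×3 corner, which sits ~2w bins closer to the
diagonal, so under pure decay the null score is (d − 2w)-ish over
(d)-ish: keeping anchor separations ≥60 bins bounds that ratio near 0.9,
and N = 2000 keeps Poisson noise on the aggregated center pixel near 2%,
so the null APA score stays within [0.8, 1.25] by design rather than by
luck. The planted score is then ≈ e × 0.9 ≈ 2.7, visibly below e because
of the same decay gradient.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: replicate and batch structure, mappability
and GC biases in peaks and matrices, inter-chromosomal contacts,
overlapping raw peak calls, multi-pixel loop clusters, nested or
overlapping TADs, correlated expression noise, and any realistic
gene-density or annotation complexity. Recovery being exact here means
the operations compose correctly, not that real anchors are this clean.

## Numerical and design choices

- **Containers.** In-memory objects are 1-based closed `GRanges` (the
  Bioconductor convention); BED-family readers/writers convert at the IO
  boundary, preserving half-open overlap semantics exactly. The interval
  algebra delegates to `IRanges`/`GenomicRanges` (`findOverlaps`,
  `reduce`) and is checked against per-base bit-vector oracles in the
  tests.
- **One label per peak.** Feature annotation is decided at the peak
  midpoint with precedence promoter > 5'UTR > 3'UTR > exon > intron >
  downstream > intergenic; UTR calls need CDS bounds (BED12
  thickStart/thickEnd) and collapse into `exon` without them. Introns are
  numbered in transcription order, so intron 1 of a `-` gene is its
  rightmost intron.
- **Marks beat gene features** in anchor display classes (`p300only` >
  `H3K27me3` > feature); the p300-only/H3K27me3 anchoring fraction
  requires the two marks on *opposite* anchors, with a `same_anchor`
  option (off by default) to also count co-occurrence.
- **Rank tests.** `rank_sum_test` uses midranks, a tie-corrected variance
  and a 0.5 continuity correction; for tie-free samples with n₁+n₂ ≤ 10
  it switches to full enumeration of all rank assignments (two-sided p =
  2·min of the tail probabilities, capped at 1). `kruskal_wallis` applies
  the standard tie correction; for two groups its H equals z² of the
  uncorrected rank-sum z. Both are validated against enumeration, the
  exact Mann-Whitney distribution, and `wilcox.test`/`kruskal.test`. Tests
  are two-sided throughout, and no multiple-testing correction is applied
  inside the package (the analyses report single headline comparisons).
- **VC_SQRT.** Entries are divided by √(row sum)·√(column sum); all-zero
  rows are left untouched and flagged; the result is rescaled by one
  constant to preserve the mean non-zero entry. Ratio-based scores (APA)
  are invariant to that constant, and doubling every raw count leaves the
  APA score unchanged.
- **APA.** The loop pixel is the midpoint bin of each anchor, oriented
  with the lower-coordinate anchor as the row; loops within 2w bins of
  the diagonal or whose window leaves the matrix are skipped and counted
  by reason; the corner block size (default 3) is configurable. Whether
  virtual 4C uses raw or balanced counts is the caller's choice and is
  recorded in the output.
- **merge_loops** keeps the first-encountered representative among loops
  whose anchor centers both fall within `slack` (default one bin), the
  tolerance being otherwise unspecified in the field's merge tools.
- **Degenerate inputs.** Empty peak sets are valid (flags are all-false);
  an empty loop list or an all-zero matrix is an explicit error; duplicate
  expression ids resolve to the maximum TPM with a message; gene ids
  missing from the expression table are dropped and counted.

## Problem sizes

The shipped test suite and acceptance script run entirely on the
synthetic genome: 2 × 10 Mb chromosomes (400 bins each), 200 loops, 60
TADs, 400 genes; 100 simulations for rank-test power, 2,000 for null
calibration, 20 seeds for APA null scores, and 1,000 randomized
interval-algebra cases against the per-base oracle. These sizes make
every recovery property exactly checkable while keeping a full run in the
low minutes on one core.

## Limitations

The package ingests plain-text formats only (`.hic`/`.cool` binaries,
bigWig/bigBed and GTF/GFF are out of scope, as are liftover, loop/TAD
calling, insulation scores, ICE/KR balancing and motif analysis). The
head-to-tail "3' region" is operationalized as the TES ±5 kb terminator
window, with a gene-body fallback behind `body_as_terminator`; exact
reproduction of published boundary-gene counts depends on the gene
annotation and oncogene catalogue supplied by the user, which is why both
are explicit inputs and every run records its resolved inputs.
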