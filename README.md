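# anchorloops

Chromatin loops are usually pictured as activating contacts between
enhancers and promoters. A distinct, repressive configuration pairs a
**p300-only peak** — a p300 binding site with no H3K27ac within ±1 kb —
on one anchor with a **PRC2/H3K27me3-marked promoter** on the other, and a
related **head-to-tail** arrangement places two same-strand genes at the
two boundaries of one TAD, the upstream gene's 3' end on one boundary and
the downstream gene's promoter on the other, with the downstream gene
restraining its partner. `anchorloops` is an R/Bioconductor-style toolkit
for finding and quantifying both configurations genome-wide, for anyone
analyzing ChIP-seq peak sets together with Hi-C loop/TAD calls and
expression tables.

The package provides, end to end:

- **Interval algebra and IO** (`read_intervals`, `read_pairs`,
  `read_genes`, `slop`, `filter_nonoverlapping`, `merge_intervals`):
  BED3/6/12, narrowPeak, BEDPE, bedGraph and chrom.sizes readers/writers
  on top of `GRanges`, with BED half-open overlap semantics.
- **p300-only peaks** (`derive_p300_only`): p300 peaks that survive
  exclusion by H3K27ac peaks extended ±1 kb, plus midpoint feature
  annotation (`annotate_features`) with transcription-ordered intron
  numbering, and signal profiles around peak centers (`signal_profile`).
- **Anchor classification** (`annotate_anchors`, `classify_interaction`,
  `interaction_census`, `mark_fraction`): each loop anchor or TAD-boundary
  window (boundary ±5 kb) is labelled p300only / H3K27me3 / Promoter
  (TSS ±1 kb) / Terminator (TES ±5 kb) / Genebody / Intergenic; pairs are
  censused and the fraction anchored by p300-only and H3K27me3 on opposite
  anchors is reported.
- **Head-to-tail detection** (`detect_head_to_tail`, `oncogene_scan`):
  same-strand gene pairs whose terminator and promoter windows hit the two
  boundary windows of one TAD, in transcription order.
- **Expression comparison** (`compare_groups`, `rank_sum_test`,
  `kruskal_wallis`): log2(TPM+1) comparisons between anchor-defined gene
  groups with self-contained, tie-corrected rank tests (exact enumeration
  for small tie-free samples).
- **Hi-C operations** (`load_contact_matrix`, `vc_sqrt_normalize`,
  `virtual_4c`, `apa`): plain-text COO matrices at fixed resolution,
  VC_SQRT balancing (entry divided by the square roots of its row and
  column sums), virtual-4C viewpoint profiles, and aggregate peak analysis
  with a center-versus-lower-left-corner enrichment score (default 25 kb
  bins, window 6).
- **A synthetic-data generator** (`synthetic_config`, `generate_dataset`,
  `generate_contact_matrices`): a toy genome with planted repressive
  loops, head-to-tail TADs, expression deficits and distance-decay Poisson
  contact matrices, plus the ground truth to verify recovery.

## Worked example

Everything below runs offline on the package's own synthetic genome
(two 10 Mb chromosomes, 25 kb bins, 200 loops of which 10% are planted
p300-only/H3K27me3 pairs, 5 head-to-tail TADs):

```r
library(anchorloops)

cfg  <- synthetic_config(seed = 7)
ds   <- generate_dataset(cfg)
mats <- generate_contact_matrices(cfg, ds$tads, ds$truth$planted_pixels)
report <- run_pipeline(pipeline_config(), dataset = ds, matrices = mats)
```

```
[p300only] 90 p300 peaks vs 100 H3K27ac peaks (extend 1000 bp)
[p300only] 40 p300-only peaks
[classify-loops] 200 loops; 10.00% p300only-H3K27me3 anchored
[expr-compare] H3K27me3 n=20 median=2.98 vs nonH3K27me3 n=20 median=4.00, p=0.00905
[apa] 20 qualifying loops, score 2.810
[classify-boundaries] 60 TADs -> 120 boundary windows
[headtail] 5 head-to-tail pairs
[expr-compare] Kruskal-Wallis H=1.53 p=0.466
```

Reading the log: of 90 p300 peaks, the 40 planted standalone ones survive
the extended-H3K27ac filter; exactly the planted 10% of loops are called
p300-only↔H3K27me3 (`report$loops$mark_fraction$percent` is `10`); genes
looped to p300-only anchors and marked by H3K27me3 run about one
log2(TPM+1) unit below their unmarked counterparts (medians 2.98 vs 4.00,
rank-sum p = 0.009); and the aggregate-peak-analysis score of the
qualifying loops is 2.81 against the planted 3-fold pixel enrichment
(attenuated by Poisson noise and the decay gradient). The interaction
census is in `report$loops$census`:

```
Intergenic-Terminator Intergenic-Intergenic Terminator-Terminator
                   53                    34                    23
    H3K27me3-p300only     Promoter-p300only   Genebody-Intergenic
                   20                    20                    15
                  ...
```

On real data, replace the dataset with file paths in `pipeline_config()`
(gene BED12, narrowPeak peaks, BEDPE loops, BED TADs, TSV expression,
COO-text matrices and a chrom.sizes file).

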