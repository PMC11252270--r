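---
title: "Super-enhancer calling and target nomination: models, parameters, design"
author: "secanalyze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer calling and target nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secanalyze)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic data emulate (and what they do not), and the design choices made
where the design was genuinely open.

## The super-enhancer model

Super-enhancers are large clusters of enhancers carrying disproportionately
high H3K27Ac signal; ranked by signal, enhancer landscapes form a
"hockey-stick" curve whose inflection separates typical enhancers from SEs.
The calling chain is the ROSE construction:

1. *Promoter exclusion.* H3K27Ac peaks fully contained within
   ±`promoter_flank` (default 2500 bp) of any TSS are discarded. We read
   "not contained within" literally — a peak that merely overlaps a
   promoter flank is kept intact, because its enhancer portion still
   carries signal; `mode = "any"` in `exclude_promoter_regions()` gives
   the stricter alternative.
2. *Stitching.* Remaining regions with gaps ≤ `stitch_gap` (default
   12 500 bp, inclusive: "within 12.5 kb" is read as ≤) merge
   transitively. Internally this is `GenomicRanges::reduce()` with
   `min.gapwidth = stitch_gap + 1`; the test suite checks it against a
   brute-force transitive-closure oracle (connected components of the
   pairwise adjacency graph).
3. *Quantification.* Each stitched region's signal is total treatment
   coverage minus total input coverage, each scaled to reads per million,
   floored at zero **per region**: `max(0, Σ_bp chip/N_c·10⁶ −
   Σ_bp input/N_i·10⁶)`. Flooring per region (not per bp) matches the
   "total background subtracted" phrasing; `floor = "per_bp"` is offered
   for sensitivity analyses (it can only increase the signal). The
   subtraction happens after stitching, over the stitched regions —
   whether the original analysis subtracted before or after stitching is
   not documented, and after-stitching is the formulation under which the
   total is well defined. Bases outside a track's coverage count as zero.
4. *Geometric inflection cutoff.* Regions are sorted by increasing signal;
   ranks and signals are min–max scaled onto the unit square, and the
   cutoff is the point maximizing `x − y` — exactly the point where a line
   of slope 1 is tangent to the curve from below, the standard geometric
   reading of "the inflection point" for this monotone convex-tailed
   curve. It is computed as a discrete argmax, with no numerical
   differentiation to go unstable. Ties (within 1e-12 on the unit square;
   exact float equality would make tie-breaking a rounding accident)
   break toward the **larger** rank, i.e. fewer SEs — the conservative
   choice. Regions strictly above the cutoff rank are SEs.

   Degenerate inputs: identical signals cannot be min–max scaled, and a
   perfectly linear curve has `x − y ≡ 0`; both yield zero SEs with a
   `degenerate` flag rather than an arbitrary cutoff. Note that a
   landscape with no *planted* contrast is not automatically degenerate:
   stitched-region signal is a total, so region-size variation alone
   spreads the ranked totals. The flag describes the curve, not the
   generating process.
5. *Gene assignment.* Every transcriptionally active TSS within
   `assign_window` (default 50 000 bp) of an SE **edge** is
   SE-associated. Measuring from edges rather than centers is the
   assumption that makes the window meaningful for multi-kilobase SEs;
   it is configurable. Activity is an input flag on the annotation —
   the expression threshold defining "transcriptionally active" belongs
   to the expression data, not to this package — and
   `set_active_genes()` derives it from any expression table.

## Occupancy, dependent peaks, nomination

Factor occupancy uses the same 50 kb TSS-window convention as SE
assignment, for symmetry (the occupied-gene rule behind published counts
is typically unstated; `mode = "nearest"` gives the ChIPseeker-style
nearest-gene alternative). A *dependent peak* is a reference-condition
peak with no overlapping peak (≥ `min_overlap`, default 1 bp — the
strictest definition of loss) in the depleted condition. Nomination is
plain set algebra: SE-associated ∩ occupied ∩ direction-filtered DEGs,
with all pairwise cardinalities reported and checked for
inclusion–exclusion consistency after every pipeline run.

## The marker criterion

For cluster markers and within-cluster condition contrasts alike, a gene
passes when

* fold change ≥ 1.28 (or ≤ 1/1.28 for the down direction), where fold is
  the ratio of group means of `expm1`(log-normalized expression) with a
  pseudocount of 1 in numerator and denominator (the standard marker-fold
  convention; the source criterion names no formula);
* more than 25% of cells of the *overexpressing* group express the gene
  (count > 0);
* the two-sided Wilcoxon rank-sum p-value on normalized expression is
  < 0.01, **uncorrected** — the criterion is stated on raw p-values.
  `adjust = "BH"` is available but off by default.

Normalization is per-cell library scaling to a common target sum (10⁴)
followed by `log1p`. The rank-sum p-value uses the normal approximation
with tie correction and continuity correction, identical to
`stats::wilcox.test(exact = FALSE)`, vectorized over genes;
`wilcox.test` itself serves as the oracle in the unit tests.

One wrinkle deserves a note: applying the 25% filter to the *target*
group verbatim would break the natural antisymmetry of a two-condition
contrast (swapping condition labels must swap the up and down lists).
The criterion is defined for upregulated markers, where the target group
*is* the overexpressing group; we therefore attach the filter to the
overexpressing group in general, which is identical for up-markers and
antisymmetric overall. `pct_group = "target"` restores the literal
reading.

## 3C-qPCR normalization

Quantities from equal-input 3C libraries are normalized within each
(condition, replicate) to the short-range ligation control fragment:
`IF = q/q_ctrl × 100`. This cancels cross-linking and ligation
efficiency differences between samples by construction, so the control
sits at exactly 100% in every replicate and the whole profile is
invariant to rescaling any replicate. Condition comparisons report the
ratio of mean IFs per fragment with a two-sided Welch t-test on the
replicate IFs (the figure-level ANOVA/Dunnett machinery of a full study
is out of scope; `stats::aov` + multcomp remain available to users).
Fewer than 3 replicates: ratio only, p omitted. Zero-variance
replicates: exact ratio, degenerate-flagged p. Input is post-qPCR
quantities; `ct_to_quantity()` converts Ct values under perfect-doubling
if needed.

## What the synthetic data emulate

The generators produce the *shape* of the real inputs with planted,
manifest-recorded truth:

* `simulate_annotation()` — one 50 Mb chromosome, 400 genes, 70% active.
  TSSs are stratified-uniform (one per equal slot, guaranteeing
  collision-free spacing); real gene density is clustered, not uniform.
* `simulate_enhancer_landscape()` — 20 SE loci of 3–8 constituents
  (gaps 1–8 kb, always below the stitch gap, so each locus stitches into
  exactly one region) anchored 4–15 kb downstream of designated active
  genes, among 400 isolated typical enhancers; treatment coverage is
  Poisson per 50 bp bin at 0.5 reads/bp over typical peaks and 20× that
  over SE constituents; input is flat Poisson at 0.05 reads/bp. Library
  sizes include the unemitted genome-wide background, as a sequencing
  run's would; the emitted bedGraphs cover peaks only (uncovered bases
  are zero by contract). Entities are placed > 12.5 kb apart and outside
  promoter windows so planted counts survive the exclusion and stitching
  stages exactly — real landscapes are messier in precisely the ways the
  promoter-exclusion and containment rules exist to handle.
* `simulate_counts()` — negative-binomial counts (size 2, lognormal
  baseline means around 2) for a 1200-cell, two-cluster design with both
  conditions in each cluster; planted 4-fold markers and 3-fold condition
  effects comfortably satisfy the 1.28-fold/25% criterion in expectation.
  No dropout model beyond the NB zeros, no batch structure, two clusters
  rather than eleven.
* `simulate_3c()` — lognormal (unit-mean, CV 10%) quantities anchored on
  the control fragment, with a 3× planted condition effect at the E2-like
  fragment 10 kb downstream of the anchor.

Passing tests on these data demonstrate that the *inference chain* is
correct — stitching, cutoff geometry, rpm arithmetic, criterion logic,
normalization — not that the pipeline is robust to alignment artifacts,
copy-number bias, doublets, or the other failure modes of real data that
peak callers and QC pipelines exist to absorb.

Problem sizes throughout (420 enhancers, 1000–3000 genes × ≤ 1200 cells,
200 peaks, 4 replicates) were chosen as the smallest scales at which every
statistical check is well powered.

## Numerical and degenerate-input choices

* Coordinates are `GRanges` (1-based closed) internally — the R/Bioconductor
  standard — with BED/narrowPeak/bedGraph converted at the I/O boundary;
  `genomic_intervals()` accepts 0-based half-open directly. Chromosome
  names match as exact strings; no "chr" aliasing.
* Strand is carried but ignored by merging, overlap, and windows:
  H3K27Ac regions are unstranded.
* bedGraph does not encode library size; `read_bedgraph()` accepts it
  explicitly and otherwise infers `sum(value × width)` (exact when the
  track stores per-bp read counts, as the generator's tracks do).
* All-zero cells get size factor 1 (with a warning) instead of NaNs.
* An empty peak set flows through the pipeline to an empty result rather
  than an error; an empty gene set disables promoter exclusion with a
  warning.
* Every generator takes an explicit seed, restores the caller's RNG
  state, and is bit-reproducible given (parameters, seed); the pipeline
  derives stage seeds as fixed small offsets of the master seed and
  records them in the manifest.

## Known limitations

* The occupancy rule reproduces published gene *counts* only to the
  extent the original annotation rule matched a 50 kb window; that rule
  is rarely printed, which is why it is configurable.
* The condition-DEG thresholds mirror the cluster-marker criterion; the
  original contrast's thresholds are unstated, so replays of published
  up/down counts are best-effort by construction.
* The inflection cutoff assumes a monotone curve with a convex tail; on
  landscapes that are nearly linear the SE set is small and unstable by
  nature, which is what the degenerate flag surfaces.
* 3C comparisons treat fragments independently; no distance-decay model
  is fitted.
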