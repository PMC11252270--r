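# secanalyze

Super-enhancer calling and target nomination for osteoclast regulatory
genomics.

## The problem

During osteoclastogenesis, a chromatin remodeler can drive lineage
commitment by activating a master transcription factor through a
super-enhancer (SE). Nominating that target computationally takes a chain
of standard but fiddly regulatory-genomics steps:

1. **Super-enhancer calling** from H3K27Ac ChIP-seq (ROSE-style): discard
   peaks fully contained in ±2.5 kb promoter flanks, stitch the remaining
   regions when their gap is ≤ 12.5 kb, quantify each stitched region's
   background-subtracted occupancy in reads per million
   (`max(0, Σ chip/N_chip·10⁶ − Σ input/N_input·10⁶)`), rank regions by
   increasing signal, and place the SE cutoff at the geometric inflection
   of the hockey-stick curve — after min–max scaling ranks and signals to
   the unit square, the point maximizing `x − y` (the discrete slope-1
   tangent point). Regions above the cutoff are SEs.
2. **Gene assignment**: every transcriptionally active TSS within a 50 kb
   window of an SE edge is SE-associated.
3. **Factor occupancy**: a gene is occupied when a factor peak falls within
   50 kb of its TSS; **dependent peaks** are reference-condition peaks with
   no overlapping peak after depletion of the remodeler.
4. **Cluster-restricted differential expression** in scRNA-seq: a gene
   passes when it is ≥ 1.28-fold changed, expressed in > 25% of the cells
   of the overexpressing group, and its two-sided Wilcoxon rank-sum
   p-value is < 0.01.
5. **Nomination**: the triple intersection of SE-associated genes,
   factor-occupied genes, and direction-filtered DEGs.
6. **3C-qPCR normalization**: interaction frequencies reported as percent
   of the short-range ligation control within each replicate
   (`IF = q/q_ctrl × 100`), then compared across conditions.

`secanalyze` implements this chain as composable R functions on
Bioconductor containers (`GRanges`, sparse `Matrix`), plus a synthetic-data
module that generates every input with a planted ground-truth manifest, so
the whole pipeline is testable at desk scale.

## Worked example

Simulate an enhancer landscape with 20 planted SE loci among 400 typical
enhancers (20:1 per-bp signal), then call SEs and assign genes:

```r
library(secanalyze)

anno <- simulate_annotation(seed = 1)              # 400 genes on a 50 Mb chromosome
land <- simulate_enhancer_landscape(anno, seed = 7)
res  <- run_se_pipeline(land$peaks, anno$genes, land$chip, land$input)
print(res$se_call)
#> se_call: 420 enhancers, 20 super-enhancers (cutoff rank 400, 221.56 rpm)
length(res$assignment$genes)
#> [1] 22
```

420 stitched regions survive promoter exclusion; the inflection cutoff
lands at rank 400 (221.6 rpm of background-subtracted H3K27Ac), so the 20
regions above it — exactly the planted loci — are called super-enhancers,
and 22 active genes lie within 50 kb of one (the 20 designated genes plus
2 bystanders).

The full nomination analysis, end to end:

```r
rep <- run_nomination_pipeline("out/", seed = 1)
rep$cardinalities
#> $n_se       24   # SE-associated genes
#> $n_occupied 60   # factor-occupied genes
#> $n_deg      33   # downregulated in the target cluster after knockout
#> $n_se_occ    8   # SE-associated AND occupied
#> $n_triple    1
rep$nominated
#> [1] "gene_0293"  # the planted SE-driven, occupied, downregulated target
```

`out/` contains `report.json`, per-stage TSV/BED outputs, the resolved
configuration, and the simulation inputs with their `manifest.json`.

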