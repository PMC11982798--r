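# fixcurate

Fixation-aware curation and drought-response analysis of plant single-cell
transcriptomes.

## The problem

Plant single-cell RNA-seq needs enzymatic cell-wall digestion to release
protoplasts, and the digestion itself triggers a transcriptional response
that contaminates — and can even invert — the biology under study.
Fixing the transcriptome with actinomycin D during digestion suppresses
the artifact, but a fraction of cells *escape* fixation and still mount
the full digestion program. `fixcurate` is for analysts of such data: it
derives a cell-wall-digestion gene signature from a factorial bulk
RNA-seq design, scores every cell against it, removes escape cells, and
profiles tissue-specific and dual mesophyll drought responses on the
curated atlas.

## The method in brief

**Bulk arm** — digestion treatment (undigested U, digested D,
fixed-digested FD) × watering regime (WW, MD):

- median-of-ratios size factors; per-gene NB Wald test
  (`log2FC = log2(μ_b/μ_a)`, delta-method SE, method-of-moments
  dispersion floored at the cross-gene median), BH-adjusted, DEGs at
  FDR < 0.05;
- digestion × condition interaction via an NB likelihood-ratio test
  (`~ digestion * condition` vs `~ digestion + condition`, χ² df = 2,
  interacting set at p < 0.05);
- digestion DEGs clustered on `1 − Kendall τ_b` between per-group mean
  profiles (PAM, silhouette-selected k); the induced cluster, minus
  interaction and drought-responsive genes, ranked by FDR and truncated
  to 250, is the **digestion signature**;
- audit operations: directional DEG counts, opposite-direction fold-change
  audits with integer percentages, overlap enrichment (fold over
  expectation + χ² p), exclusive UpSet intersections.

**Single-cell arm** — QC (≥ 1000 genes, ≥ 1250 UMIs by default), per-sample
gene filter (< 5 cells), library-size log-normalization; per-cell
**module score** = mean signature expression − mean of 50
expression-matched control genes per signature gene drawn from 25
abundance bins; escape threshold from a 2-component Gaussian mixture
(equal-posterior cut, nothing flagged if BIC prefers one component);
curation bookkeeping; Wilcoxon tissue-level drought DE
(p < 0.05, |log2FC| > 0.75, ≥ 5 % detection in the induced side),
pseudobulk NB DE (p < 0.05, log2FC > 0.5), dual canonical-ABA /
iron-starvation program labelling with per-program mixture cut-offs, and
detection-set coexpression (Jaccard) for program exclusivity.

A synthetic-data generator (`simulateBulk()`, `simulateCells()`) plants
all of this structure — digestion programs attenuated or amplified by
fixation, drought programs, sign-flip interaction genes, escape cells,
and two mutually exclusive mesophyll drought programs on a latent
gradient — with full ground-truth labels, so every stage is testable.

## Worked example

```r
library(fixcurate)
cfg <- simConfig(seed = 1)   # the default study design
rep <- runPipeline(cfg)
```

The run report prints (seed 1):

```
digestion DEGs: 219
interacting genes: 140
drought DEGs (U): 183 (122 up / 61 down)
opposite-direction in D: 33 %
opposite-direction in FD: 2 %
signature size: 119
FD cells: 993 -> flagged 230 (23%) -> curated atlas 763
dual programs: canonical=46, iron=60, shared=0, none=91
coexpression cross/within program: 0.019 / 0.830
```

Reading this: the Wald test finds the planted digestion response (219
DEGs over 250 planted digestion-responsive genes); the LRT flags the
sign-flip interaction genes. Of the drought DEGs found in undigested
samples, 33 % point the *wrong way* in unfixed protoplasts but only 2 %
under fixation — the artifact the curation exists for. The derived
signature (119 genes after exclusions) then flags 23 % of fixed-digested
cells as fixation escapees (the planted fraction is 24 %); after their
removal, the two mesophyll drought programs separate cleanly: genes from
different programs are co-detected in 1.9 % of cells (Jaccard), genes
from the same program in 83 %.

Individual stages are exported (`nbWaldTest`, `nbInteractionLRT`,
`clusterProfiles`, `deriveSignature`, `moduleScore`, `digestionScore`,
`curateCells`, `tissueDroughtResponse`, `dualProgramDetection`, ...) and
work on any `SummarizedExperiment` / `SingleCellExperiment` with the
appropriate design columns; `readCellTable()` / `writeCellTable()` move
cell data through Matrix-Market + TSV, `readBulkCounts()` through plain
TSV, and `readSimConfig()` loads a YAML configuration.

See `vignettes/fixation-aware-curation.Rmd` for the full model
description, parameter rationale, and limitations.

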