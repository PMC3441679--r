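---
title: "Quantifying chromosome-wide chromatin enrichment with xachrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromosome-wide chromatin enrichment with xachrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xachrom)
```

## The problem

In *C. elegans* hermaphrodites, the dosage compensation complex (DCC) binds
both X chromosomes and halves X-linked transcription. One chromatin
signature of this process is mono-methylated histone H4 lysine 20
(H4K20me1): it is enriched chromosome-wide on the hermaphrodite X, over
genes and intergenic space alike, and the enrichment collapses in DCC
mutants such as *dpy-21* and in *set-4* mutants. `xachrom` implements the
quantitative side of that analysis as reusable, tested components: turning
ChIP/Input signal into comparable z-score tracks, summarizing them per
chromosome, profiling them around gene anchors and intergenic centers,
scoring ectopic spreading across a fusion-chromosome junction, and
estimating expression fold changes by relative qPCR. A synthetic-data
generator with known ground truth exercises every stage end to end.

## Signal model and processing order

The unit of analysis is the **z-score track**: per-bin
log2(ChIP/Input) ratios standardized so a *reference chromosome set* has
mean 0 and standard deviation 1. For X-enrichment analysis the reference is
the autosomes, so X values are expressed in autosomal standard deviation
units and an X-wide shift is directly readable; for marks depleted on X
(e.g. H4K20me3) the whole genome is the natural reference, and both choices
are exposed (`standardize(reference = "autosomes"|"all")`).

Processing follows a fixed order, which matters and is applied by
`runEnrichmentPipeline()`:

1. `log2Ratio()` (only for raw-count inputs; pseudocount 1 by default),
2. `standardize()` each biological replicate,
3. `averageTracks()` across replicates *after* standardization,
4. `medianSmooth()` with a 1 kb window along each chromosome,
5. `chromosomeSummary()` / `xaEnrichment()`.

Standardization uses the population standard deviation (divide by *N*;
with track sizes in the 10^4–10^6 bin range the distinction from the
unbiased form is immaterial, but fixing it makes the mean-0/sd-1 contract
exact and testable to 1e-9). Percentile summaries use linear interpolation
between closest ranks (`quantile()` type 7, the default of the common
scientific numeric stacks). Median smoothing uses a centered window
truncated at chromosome ends — no padding, because chromosomes do not wrap —
and the window always spans an odd number of bins
(`2*floor(window/(2*res)) + 1`). Missing bins are excluded from every
moment, median and percentile, and never imputed; replicate averaging
tolerates one missing replicate per bin and otherwise propagates
missingness.

`xaEnrichment()` is the scalar summary of the chromosome-level contrast:
median over X bins minus median over all autosomal bins pooled. A pooled
autosomal median (rather than a median of per-chromosome medians) weighs
each autosomal bin equally, which is also why the function operates on the
track rather than on the per-chromosome summary table.

## Profiles

Meta-gene profiles align genes at the TSS or TES, strand-aware, with the
conventional windows (TSS: 1 kb upstream / 1 kb downstream; TES: 1.5 kb /
1 kb) divided into 50-bp bins — 40 and 50 columns respectively. A profile
bin's value is the bp-weighted mean of the track bins it overlaps, which
makes profiles independent of the track's native resolution; window parts
outside the chromosome are missing. Anchors are boundary coordinates (the
5' edge of the anchor base), so a plus-strand and a minus-strand gene
anchored at the same genomic boundary produce exact mirror-image rows.

Genes are stratified into the top and bottom 20% by expression within each
chromosome class (`assignGroups()`). Ranking X genes among X genes keeps
the four plotted groups proportional to class size; a `quantileScope =
"global"` switch ranks across classes instead, since either reading of
"top 20% expressed" is defensible. Group sizes are `floor(0.2 n)` and ties
break lexicographically by gene id, so the assignment is deterministic.
Genes shorter than the window are profiled like any other; no length filter
is applied. Per group and bin, the summary reports the mean and a 95%
normal-approximation CI (`1.96 * sd / sqrt(n)`, sample sd); at the group
sizes this machinery is meant for (hundreds to thousands of genes) the
difference from a t-interval is negligible, and the CI is left undefined
for `n < 2`.

Intergenic profiles use `findIntergenic()`: maximal intervals of at least
10 kb containing no annotated feature of any kind on either strand — a
deliberately conservative reading of "annotation-free" — aligned at their
centers (floor convention for even lengths) with a 5 kb flank on each side
(200 columns). These regions show whether an X-wide signal extends beyond
genes.

Internally all interval work uses `GRanges` (1-based closed, the
Bioconductor convention); BED's 0-based half-open and GFF3's 1-based closed
coordinates are converted at I/O by `rtracklayer`, and round-trips are
exact. All window arithmetic inside the signal code is done in 0-based
offsets, so the two conventions never mix.

## Fusion-chromosome spreading

`buildFusion()` joins two full-length chromosomes end to end (X forward,
then the autosome forward), which is all the spreading assay needs: a
coordinate frame with a defined junction. Exact strain breakpoints, when
known, can be encoded with `FusionMap()` segments, including
reverse-oriented ones. `spreadingScore()` is the mean z over the
autosome-derived flank just past the junction in the fusion strain minus
the mean over the *same source bases* in the normal-karyotype control —
matching control bases rather than genome-wide averages controls for local
sequence effects. `spreadingCurve()` resolves the same contrast by distance
so a decay length can be fitted.

## Expression and qPCR

Probe-level expression arrays are quantile-normalized
(`limma::normalizeQuantiles`, ties receiving the mean of the quantile
values they span) and summarized to one value per gene by the per-gene
median of its probes — a deliberately simple substitute for model-based
summarization that is sufficient when all the analysis needs is one value
per gene. Signal–expression coupling is quantified by Spearman correlation
(average ranks for ties), separately for autosomal and X-linked genes, on
bp-weighted gene-body mean z (`geneBodySignal()`).

`qpcrRelativeExpression()` implements delta-delta-Ct: replicate-mean Ct per
strain and gene, `dCt` against a reference gene (the autosomal W07G4.4 in
the original assay design, whose primer table ships in
`inst/extdata/qpcr_primers.tsv`), `ddCt` against a calibrator strain
(wild-type N2) whose fold is 1 by definition, and fold
`= efficiency^(-ddCt)` with efficiency 2 (perfect doubling) unless
calibrated otherwise. The 95% CI propagates the replicate variances of all
four Ct means into the exponent and exponentiates, giving a log-symmetric
interval; the table does not distinguish technical from biological
replicates.

## The synthetic generator

`generateGenome()`, `generateChipExperiment()`,
`generateFusionExperiment()` and `generateQpcr()` emulate the statistical
structure the analysis assumes, with every parameter in
`syntheticConfig()` and all randomness under one master seed (fixed
documented sub-stream offsets per component, so the genome, each
replicate and each assay are independently reproducible).

The default configuration *is* the study condition the recovery analyses
use: a 5 Mb autosome plus a 5 Mb X, 500 genes (uniform 1–5 kb lengths,
broken-stick gaps that naturally produce a tail of >10 kb intergenic
regions), log-normal expression, and per-bin signal

    mu = b + alpha * log2(expr)        over gene bodies
       + deltaX  * [X, genic, WT]
       + deltaIg * [X, intergenic, WT]

with `b = 0`, `alpha = 0.15`, `deltaX = deltaIg = 1.5` z units, two
replicates and Gaussian replicate noise sd 0.3. Setting the intergenic
boost equal to the genic boost makes the wild-type X a uniform additive
shift of the autosomal process, mirroring the observed chromosome-wide
enrichment of similar magnitude over genes and intergenic space, and it
makes the pooled-median contrast an unbiased estimator of the shift. The
`dcc-mutant` genotype zeroes both X boosts; `set4-like` zeroes them and
raises the baseline globally.

Because the generator's effect sizes are declared in z units — the unit of
already-standardized tracks — the emitted log2-ratio tracks should look
like standardized data. A bin-level background component, shared across
replicates and genotypes (locus-specific chromatin signal), is therefore
auto-calibrated so the per-replicate autosomal variance is 1. Without it
the standardization step would rescale every effect by the reciprocal of
the autosomal sd (about 2.5x under the defaults), and no z-unit parameter
could be recovered on its own scale. Set `backgroundSd = 0` to disable the
component, or give it explicitly.

Noise is Gaussian on the ratio scale because the pipeline consumes ratio
tracks; a Poisson raw-count mode (`mode = "counts"`) feeds the
`log2Ratio()` entry point instead. The fusion experiment adds
`a * exp(-d/L)` (defaults `a = 1`, `L = 100 kb`) past the junction and is
generated at 25 bp resolution, emulating per-base-pair coverage pipelines,
against 100 bp for the array-like genic tracks. The qPCR generator shifts
dosage-compensated X-linked genes down by `log2(fold)` cycles in mutant
strains (default fold 2 — the loss of two-fold repression), adds a random
strain offset that the reference gene removes, and replicate noise of sd
0.1 cycles.

What the generator does *not* emulate: mappability and GC biases,
probe-level array artifacts, autocorrelated biological domains beyond the
bin-level background, operons and isoforms, or read-level sampling.
Passing recovery tests therefore demonstrates the correctness of the
computation, not robustness to the full messiness of real ChIP data —
upstream corrections (e.g. bead-array normalization) remain the user's
responsibility.

## Problem sizes and numerics

The test-suite recovery runs use the default 10 Mb genome at 100 bp
resolution over 10 seeds, which keeps the whole suite around two minutes
while leaving the X-shift estimator's across-seed standard error near
0.005 z — small enough that a 3-standard-error recovery check is a sharp
test. Degenerate inputs are refused loudly: constant reference signal
(zero variance) in `standardize()`, all-missing chromosomes in summaries,
smoothing windows narrower than one bin, fewer than five genes in an
expression class (skipped with a warning), flanks beyond the fused
autosomal segment (truncated with a warning), and missing reference genes
or calibrator strains in qPCR tables (errors naming the strain).

## A complete run

```{r example, eval = FALSE}
cfg <- syntheticConfig()
gd <- generateGenome(cfg, seed = 1)
chip <- generateChipExperiment(gd, cfg, genotype = "WT", seed = 1)
res <- runEnrichmentPipeline(chip$chip, gd$genes, gd$expression, gd$genome,
                             outDir = "wt_run")
res$xaEnrichment          # ~1.5 in the wild type
res$summary               # per-chromosome medians and percentiles
head(res$tssProfile)      # group means with 95% CIs per 50-bp bin
```

Every written table carries a header naming the producing stage and a hash
of the parameters, and `manifest.json` records parameters, stages and
collected warnings, so a run can be reproduced from its output directory
alone.
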