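---
title: "Tile-based analysis of germline methylomes and chromatin: models and design"
author: "methTiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based analysis of germline methylomes and chromatin: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTiles)
```

# Scope

methTiles implements the tile-based statistics used to ask how loss of de
novo DNA methylation in the male germ line (conditional *Dnmt3a*/*Dnmt3b*
double knockout, "DKO") reshapes sperm chromatin and the chromatin of the
early embryo.  All stages share one coordinate system: the genome is cut
into non-overlapping 500-bp tiles, and every assay — enzymatic methyl-seq,
RRBS, ChIP-seq of nucleosomes or H3K4me3, allele-resolved tagmentation data
from hybrid two-cell embryos, and embryo RNA-seq — is quantified on those
tiles (or genes, for expression).  The package covers the statistics
downstream of alignment: read counting on tiles, filtering, differential
testing, classification, enrichment, profile matrices, and allele
assignment.  Alignment, peak calling and pseudotime estimation are upstream
tools whose outputs are inputs here.

# The tile universe

`makeGenomeTiles()` tiles each chromosome from position 0 in fixed 500-bp
steps, dropping a partial terminal tile so every tile has identical length
(constant length keeps RPKM comparable across tiles).  Coordinates are
0-based half-open in all text output; `GRanges` objects follow the usual
1-based convention internally.  `annotateTiles()` records, per tile, the GC
percentage over non-N bases and the number of CpG dinucleotides; a CpG whose
C is the last base of a tile is assigned to that tile, so boundary-spanning
dimers are counted exactly once.  Tiles more than half N are flagged
unusable.  `applyBlacklist()` removes tiles that share at least one base
with a blacklist interval; the half-open convention means an interval
starting exactly at a tile's end does not touch it.

# Differential methylation

Per-CpG methylated/unmethylated counts are destranded (plus and minus
records of one CpG merged) and summed within tiles, per sample
(`aggregateToTiles()`).  Percent methylation of a tile is the pooled
fraction of methylated reads, in percent.  Tiles enter testing when they
have at least 5 annotated CpGs and at least 25 reads in *every* sample
(`filterTiles()`); the per-sample reading of the coverage rule is the
stricter of the two possible interpretations and is reproducible from the
data alone.  RRBS presets drop CpGs under 5 reads and use a 20-read tile
filter; whole-genome data use 25.  Both CpG-filter conventions in
circulation (≥5 vs ≥4) are reachable through `minCpg`.

`testDifferentialMethylation()` models the tile-level counts of each sample
as beta-binomial with mean p and overdispersion φ, and compares a
common-mean model against group-specific means with a likelihood-ratio test
on χ²(1).  φ = 0 reduces to the binomial.  The effect size `delta_me` is
the difference of replicate-pooled percent methylation (test − reference).
DMRs are tiles with |Δme| above 25 points (20 for RRBS) and
Benjamini–Hochberg FDR below 0.05 (`callDmrs()`); a hypoDMR is a tile
losing methylation in the mutant.

**Why a pooled φ.** With two replicates per group the tile-wise moment
estimator of φ has roughly two residual degrees of freedom: it is zero for
half the tiles (the estimator is floored at 0) and wildly large for others,
and a test that plugs it in rejects ~11% of true nulls at α = 0.05 in our
simulations.  The default therefore pools the tile-wise moment estimates
into one common φ (as common-dispersion count models do), which restores the
type-I error to ~0.04 under the simulated study conditions.  `phi =
"tilewise"` and fixed numeric values remain available.

# HypoDMR trajectory groups

HypoDMRs are classified into six groups from three percent-methylation
values — a prospermatogonia (pSg) reference, control sperm, and DKO sperm —
plus GC class (GC-rich means >50% GC; exactly 50 is GC-poor).  The
published group descriptions are prose ranges; `hypoDmrCutpoints()` fixes
them numerically and every cut-point is an argument:

* groups 3/4: pSg < 20, control in [25, 50], DKO < 5 — lowly methylated
  regions that collapse further;
* groups 1/2: pSg in [10, 50], control > 50, DKO < 20 — bona fide de novo
  targets of adult spermatogenesis;
* groups 5/6: pSg in [30, 80], control ≥ 75, DKO in [25, 75] — regions
  retaining intermediate methylation.

Rules are evaluated 3/4 → 1/2 → 5/6 with first match winning: the sharp DKO
signatures of 3/4 and 1/2 are the most specific, so they take precedence
where boxes overlap.  Odd groups are GC-rich, even GC-poor.  Tiles matching
no box stay `unclassified` rather than being forced to the nearest box —
forcing would hide threshold sensitivity.

# Occupancy: normalization and differential testing

Tile counts are converted to log2 RPKM with a pseudocount of 0.5 (a zero
count in a 500-bp tile at a 1e6-read library maps to exactly 0); in allelic
mode the library size is the number of reads assigned to that allele.
`cyclicLoessNormalize()` implements the fast cyclic loess: each sample's
deviation M from the per-tile mean A is regressed on A with a robust
tricube local fit (`stats::lowess`, 3 robustness iterations) and the fit is
subtracted.  Two refinements matter in practice:

* fits are re-centred across samples before subtraction, so the per-tile
  cross-sample mean is preserved exactly (between-sample differences, the
  quantity of interest, are unchanged by centring);
* after a first fit, tiles whose residual exceeds 2 robust SD are dropped
  and the curve refit (`trim = TRUE`).  Without the trim, genuinely changed
  tiles migrate along A and locally drag the correction curve, compressing
  true fold changes by ~10%.  With `trim = FALSE` the function reproduces
  the reference fast-cyclic-loess implementation to machine precision,
  which the test suite checks against limma.

One pass (`iterations = 1`) removes constant offsets; strongly curved
biases benefit from iterating (we use 3 passes, the reference
implementation's own default, in the rescue analyses below).

`testDifferentialOccupancy()` transforms normalized values back to
pseudo-counts and applies a two-group negative-binomial likelihood-ratio
test with a single common dispersion shared across tiles, estimated by
solving the Pearson moment equation Σ(x−μ)²/(μ+φμ²) = residual df around
the fitted group means (the linearized moment estimator underestimates φ
and inflates rejections by ~1 point).  Group means under fixed φ and
per-sample offsets are fitted by a vectorized Newton solver; the suite
verifies it against `glm.fit` with the negative-binomial family.  Fold
changes are `log2((CPM_B + 1)/(CPM_A + 1))` (prior count 1); a tile is
significant at |log2FC| > 1 and raw p < 0.05 (the occupancy contrasts use
raw p; `adjust = TRUE` switches to BH).  For the embryo comparisons,
`trichotomizeLfc()` partitions fold changes at ±0.5 with values exactly at
the boundary counted unaltered.

`filterPeaks()` reproduces the external-peak filter: q < 0.01 and length
strictly below the type-7 0.99 quantile of the input lengths.

# Allelic read assignment

In a JF1 × C57BL/6 hybrid, each aligned read is compared with the SNP table
at the positions it overlaps: a read base equal to the maternal allele adds
one mismatch against the paternal haplotype and vice versa; a third base
counts against both.  Reads are `maternal`/`paternal` by strictly fewer
mismatches and `undefined` on ties — including reads overlapping no SNP.
Restricting the comparison to SNP positions of a single alignment gives the
same calls as aligning to both SNP-substituted genomes and comparing total
mismatch counts, because non-SNP positions contribute identically to both;
`assignAlleleDual()` accepts precomputed dual-alignment mismatch columns for
pipelines that do align twice.  Allelic library sizes count assigned reads
only.  With a per-base error rate e, a read overlapping one SNP is
misassigned when the error hits the SNP and produces the other strain's
base, probability e/3 — the generators reproduce this and the suite checks
it within a 3-SE binomial band.

# Profiles

`profileMatrix()` counts read positions into 51-bp bins around tile
centers.  10 kb is not a multiple of 51, so the matrix uses the smallest
odd number of bins whose span covers ±5 kb: 197 bins spanning ±5023.5 bp,
with the center bin straddling the midpoint.  Smoothing replaces each bin
by the mean of the 21-bin window centred on it (10 bins each side, window
intersected with valid columns at the edges).  Unstranded RNA tiles are
oriented so the heavier half of the signal points right; ties are left
unflipped and the operation is idempotent.  Group averages are column
means; smoothing and averaging commute, which the suite asserts.

# Expression with a pseudotime covariate

Embryo RNA-seq counts are filtered at CPM ≥ 1, then modelled per gene as
negative binomial (log link, offset log library size) with design
`~ 0 + genotype + ns(pst, 3)`.  The natural-spline basis places boundary
knots at the pseudotime range and internal knots at the 1/3 and 2/3
quantiles: one knot per sample would over-parameterize a ~14-embryo design,
while quantile knots keep 3 identifiable columns, and the natural
constraint makes the fitted trend linear beyond the observed range.  The
genotype contrast is tested by a likelihood-ratio test against a reduced
design whose two genotype columns are pooled into one (df = 1) — this
tests the genotype difference while leaving the developmental trend free.
Dispersion is one common Pearson-equation estimate across genes.
Significance is |log2FC| > 1 with BH FDR < 0.05.  `permutationControl()`
refits the model with pseudotime permuted across samples and records
significant-gene counts, guarding against spline overfitting;
`stratifyByExpression()` provides the quartile stratification used for
signal-by-expression displays (type-7 quantiles, ties down).

# What the generators emulate

All generators are deterministic functions of a seed carried in
`simulationConfig()`; each generator derives its own fixed sub-seed so
adding one does not shift another.

**Methylome** (`simulateMethylome()`): a synthetic chromosome of 6,200
tiles — 200 per trajectory group plus 5,000 nulls, interleaved — with
two replicates each of pSg, control and DKO.  Per-tile truth triplets are
drawn from boxes strictly interior to the classification regions (interior
margins of roughly three standard errors of a pooled percent estimate at
the simulated coverage), and the control-vs-DKO gap is kept above 25 points
plus noise so every planted tile is a genuine hypoDMR; nulls share one
level across conditions.  Per-CpG depths are Poisson with mean 30 reads per
CpG — "coverage" is per-CpG sequencing depth — and methylated counts are
beta-binomial with φ = 0.02 across replicates.  GC-rich tiles carry 15–25
CpGs, GC-poor 6–14, so the coverage filters bite realistically.

**Occupancy** (`simulateOccupancy()`): 5,000 tiles, log-normal baseline
intensity (mean log2 = log2 100, SD 0.6), NB dispersion 0.1, 2 vs 2.  100
tiles (2%, the order of the differential fraction seen in tile analyses of
this kind) carry ±2 log2 effects with balanced signs — balanced because
gains and losses occur in comparable numbers in such contrasts, and because
one-sided planting would distort library composition by ~15%, a property of
the generator rather than of the methods.  The optional efficiency bias
adds amplitude·sin(A) (log2 scale, A = true intensity, amplitude 0.75,
about 1.7-fold at the extremes) to a configurable set of samples.  A bias
confined to one sample of four is provably self-normalizing under the
pooled-dispersion two-group test — the group mean absorbs half of it and
the common dispersion the rest — so the rescue analysis applies the bias
coherently to both samples of one group, the batch-confounded-with-group
scenario that normalization exists to protect against.

**Hybrid reads** (`simulateAllelicReads()`): a 100-kb random chromosome,
SNPs at 1 per 200 bp forming the maternal haplotype, 20,000 100-bp reads
drawn evenly from both haplotypes, optional per-base error rate.

**Expression** (`simulateExpression()`): 2,000 genes, 7 embryos per
genotype.  Pseudotimes are evenly spaced with the mutant cohort shifted by
a fixed delay of 0.3 (plus small jitter) — a systematic developmental
delay, which is the confound the spline model exists to absorb; a sampled
delay would make the confound a lottery across seeds.  Gene-wise trends are
linear-plus-quadratic in pseudotime on the log2 scale (SDs 1 and 0.5), and
5% of genes carry a genuine ±2 log2 genotype effect.

**What passing these tests does not show.**  The generators draw clean
counts at known truth: they contain no alignment or mapping artefacts, no
copy-number or GC-dependent coverage bias in the methylome, no fragment-
length structure, no correlated neighbouring tiles, and the hypoDMR groups
are planted strictly inside their classification boxes, so recovery rates
near 100% say the machinery is correct, not that real data are this easy.
Published headline counts from the deposited sequencing data (millions of
tiles, tens of thousands of DMRs) are not reproducible at desk scale; what
is reproduced exactly is the reporting arithmetic on the printed counts
(1.1% significant; 98.4% hypomethylated among significant — the published
text prints these as "1%" and "98.3%", the latter truncated where our
summaries round half-up).

# Numerical choices and degenerate inputs

* Beta-binomial likelihoods use the (p, φ) parameterization with
  α = p(1−φ)/φ; the common-mean MLE under φ > 0 is found by 1-D golden
  search on [1e−6, 1−1e−6]; p estimates are clamped away from 0/1.
* Tiles with zero coverage in an entire group are skipped and excluded from
  the BH denominator; missing p-values propagate as NA.
* The NB Newton solver guards steps to stay positive and falls back to
  Poisson when the dispersion estimate is 0; pseudo-counts are rounded
  before likelihood evaluation.
* Ties: GC exactly 50 is GC-poor; |log2FC| exactly at a trichotomy bound is
  unaltered; profile orientation leaves ties unflipped; expression strata
  send boundary ties to the lower stratum.
* `writeSummary()` rounds half-up to one decimal (floor(10x + 0.5)/10), so
  98.35 reports as 98.4.
* Degenerate 2×2 margins give Fisher p = 1 with a flag; zero cells use the
  Haldane-corrected sample odds ratio, flagged.

# Problem sizes

The suite and the acceptance script were sized to run on one CPU in a few
minutes: 2,000-tile null calibrations, the 6,200-tile end-to-end methylome
run, 5,000-tile occupancy runs, 20,000–30,000 simulated hybrid reads and
2,000-gene expression sets.  These sizes give Monte-Carlo standard errors
of ~0.003 on a 0.05 rejection rate, comfortably inside the asserted bands.

# Known limitations

* The methylation test pools one dispersion across tiles; tagwise shrinkage
  (as count-model packages do) is out of scope.
* The allelic module assumes indel-free alignments with one locus per read;
  multi-mapping reconciliation between the parental genomes is upstream.
* Occupancy significance uses raw p by design (matching the source
  convention for those contrasts); the `adjust` switch exists but changes
  the meaning of reported rates.
* The cyclic-loess trim assumes changed tiles are a small minority; with a
  large changed fraction no per-sample normalization of this kind is valid.
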