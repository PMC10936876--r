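---
title: "Methods: differential domain calling, interval enrichment, and knockdown-dependence classification"
author: "epidomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidomains)
```

# Overview

`epidomains` implements a desk-scale, fully testable version of a common
regulatory-epigenomics analysis: a growth-factor stimulus induces a
combinatorial histone mark (such as H3K9me2S10ph) at discrete genomic
regions; the analyst wants to (i) call the regions where the mark increases
significantly between conditions from replicate CUT&RUN coverage tracks,
(ii) ask whether those regions fall at enhancers of stimulus-responsive
genes more often than chance, and (iii) split the responsive genes into
those whose induction requires a nuclear kinase (lost under knockdown) and
those that do not. Every stage is exercised against synthetic data with
planted ground truth, so the package's claims about sensitivity,
specificity and calibration are themselves computed by its test suite.

# The domain caller

Coverage is analysed in fixed windows: the genome is tiled into 1-kb bins
(`makeBins()`), and each sample's track is averaged per bin
(`readCoverage()`; uncovered bases count as zero). The normalisation chain
is fixed and order-enforced:

1. **CPM** (`cpmNormalize()`): each sample's bin values are scaled to sum
   to 10^6. At bin resolution the bin-value total is proportional to the
   read total under uniform binning, which is why the column total stands
   in for library size.
2. **IgG subtraction** (`subtractControl()`): the CPM-scale background
   track is subtracted from each target sample; negative values are kept.
3. **Denylist filtering** (`applyDenylist()`): any bin overlapping an
   excluded region by one or more base pairs is dropped entirely, before
   the per-sample moments are computed.
4. **z-scoring** (`zscoreBins()`): each sample column is centred and
   scaled (sd with one delta degree of freedom) over the retained bins, to
   absorb dynamic-range differences between experiments. A zero-variance
   sample is an error, named explicitly.
5. **Smoothing** (`smoothBins()`): the mean of rolling, centred windows of
   10 bins produces the final scores. An even window cannot be symmetric;
   the default window for bin *i* is bins *i−5 … i+4*, clipped at
   chromosome boundaries with the mean over the available bins. The
   alternative anchoring (*i−4 … i+5*) is selectable via `align`.

Differential bins are found with a per-bin two-sample Student's t test
across replicates on the smoothed scores (`perBinTest()`; Welch's variant
is a flag), two-sided p values are Benjamini–Hochberg adjusted across all
bins (`bhAdjust()`), and bins passing adjusted p < 0.005 in the requested
direction are merged when book-ended — gap zero, the behaviour of
`bedtools merge -d 0` — into domains (`callDomains()`). Domains are not
re-tested after merging; significance lives at the bin level.
`summarizeDomains()` reports the count, mean length, and the fraction of
the mappable workspace covered.

Two readings of the published-style protocol are ambiguous and are exposed
as options: whether z-scoring is per sample or per condition-average (we
default to per sample, the reading that keeps the replicate t test
well-defined), and whether the t test sees smoothed or unsmoothed scores
(we default to smoothed, the "final scores"; `perBinTest()` also accepts
the z-score stage).

## Detection limits of the per-bin t test

With *n* = 3 replicates per condition the per-bin test has 4 degrees of
freedom, and BH control at adjusted p < 0.005 over ~10^4 bins requires raw
p in the 10^-4–10^-3 range, i.e. |t| of roughly 8–13. A planted shift of
2 within-replicate standard deviations yields a noncentrality of only
2/sqrt(2/3) ≈ 2.4, so such effects are essentially undetectable at this
threshold — not a software property but an arithmetic one. The window-10
rolling mean makes this sharper for short domains: a 1-bin domain's signal
is spread equally over 10 smoothed bins (diluted 10-fold) while the noise
sd shrinks only by sqrt(10). In practice domains become reliably callable
when the planted bin shift reaches ~6 smoothed-score standard deviations
for window-length domains, or very large fold changes (≈6–10× over
baseline at our default rates) for 1–2-bin domains. The package exposes
`effectFromSd()` to translate effects between the count and
standard-deviation scales, and the test suite demonstrates both the
failure of the caller below this limit and near-perfect recovery above it.

A related resolution point: because a short domain elevates every smoothed
bin whose window contains it, the called domain localises the truth only
to within half a smoothing window. `domainRecovery()` therefore reports
sensitivity and precision both with strict ≥1-bp overlap and with a
positional tolerance (default half-window, 5 kb at the defaults); the
tolerant metric is the fair one at this pipeline's resolution.

# The permutation enrichment test

`enrichmentTest()` is a permutation test of base-pair overlap in the style
of genomic association testers: the observed overlap of the query (called
domains) with an annotation category is compared with the overlap of
randomly re-placed queries. Each query segment is placed independently,
length preserved, entirely within one workspace interval, with the
interval chosen with probability proportional to its number of valid start
positions (width − length + 1) — placement is exactly uniform over all
legal positions. Placements may overlap one another; at the low query
densities this analysis operates at (domains cover ≪1% of the workspace)
this leaves the expected overlap unbiased while keeping the sampler
simple. The fold is observed/expected with expected the simulation mean,
and the empirical p values use the +1/+1 correction, so the smallest
attainable p at 1000 simulations is 1/1001. Inside the simulation loop,
overlap is computed with a prefix-sum lookup over the merged annotation
(O(log n) per placement); tests verify it against per-base counting and
`GenomicRanges::intersect()`.

`buildCategories()` assembles the annotation categories: all enhancers,
promoters, gene bodies, and "enhancers of *S*" for arbitrary gene sets
*S* — in particular the responsive / dependent / independent sets produced
by the classifier, completing the link from expression to chromatin.
Categories are strand-stripped, merged, and clipped to the workspace.

# The knockdown-dependence classifier

Counts are filtered to genes with CPM > 10 in at least two samples
(`filterGenes()`). The default differential test (`deTest()`) is Welch's t
on log2(CPM + 1); it is deliberately simple, and every classification stage
also accepts an externally computed table (gene, lfc, adjusted p), so a
negative-binomial exact test (e.g. edgeR's) can be plugged in without
touching the set logic — which is the part this package owns.
Up-regulated genes require log fold change > 0.5 *and* adjusted p < 0.05
(`callUp()`). The up set is hierarchically clustered on row-scaled
per-condition mean profiles across control, treated and treated+knockdown
(Euclidean distance, complete linkage, k = 2 by default; distance, linkage
and k are unstated in the protocol we follow and are configurable). The
candidate cluster is the one with the largest mean scaled difference
between treated and treated+knockdown; within it, genes significantly
lower under knockdown (adjusted p < 0.05, lower expression) are
*dependent*, all other up-regulated genes *independent* — the two sets
always partition the up set, by construction.

One compositional caveat the test fixtures encode: CPM is a relative
measure, so a hypothetical experiment in which *every* expressed gene is
induced would cancel its own signal. The simulation and fixtures always
include a majority of unchanging background genes, as real transcriptomes
do.

# The synthetic-data generator

`simulateGenome()` builds a miniature genome (default two 5-Mb
chromosomes): non-overlapping gene bodies placed one per block, strand
assigned at random; promoters as TSS −1000/+500 bp (a common convention —
the protocol never defines promoter coordinates); two 1-kb enhancers per
gene within 50 kb of the TSS, carrying gene links; a sparse random
denylist (~1% of the genome); workspace = genome minus denylist.

`plantTruth()` places differential domains of 1–2 bins (matching the
~1.5-kb average region scale such analyses report) on bin boundaries
within the workspace, at least 10 bins apart so they stay distinct after
smoothing. Placement weight is 1 everywhere except bins overlapping
enhancers of responsive genes, which get weight `enhancerBias` — bias 1 is
exactly uniform; the planted fraction at responsive enhancers grows
monotonically (and initially ~linearly) with the bias. Responsive genes
are a 20% sample of all genes by default; a quarter of them are planted as
knockdown-dependent.

`simulateCoverage()` draws i.i.d. per-bin counts (Poisson by default,
negative binomial optionally) at `baselineRate` (default 25), multiplied
by the domain effect in treated replicates inside planted domains, with 3
target replicates per condition (enough for the t test to be well-posed;
replicate counts for such assays are rarely reported) and a flat IgG
background track at rate 2. Coverage is emitted at exact bin resolution —
one bedGraph record per bin — because the analysis begins at binned
counts; read-level simulation would add cost without exercising any more
of the computation. By default a *single shared* IgG track is simulated:
subtracting a condition-specific background track injects per-bin noise
common to all replicates of that condition, which a replicate-level t test
cannot distinguish from signal and which destroys type-I calibration at
realistic IgG depths. With matched designs (per-condition IgG) the
generator supports `iggPerCondition = TRUE`, but the analyst should then
not expect the per-bin test to be calibrated.

`simulateExpression()` draws negative-binomial counts (default baseline
mean 200, dispersion 0.05, 4 replicates per condition) for control,
treated and treated+knockdown; responsive genes are induced
`inducedFold`-fold (default 4) in treated, and dependent genes revert to
baseline under knockdown.

What the generator does *not* emulate: fragment-length and GC effects,
mappability structure, read-level noise, correlated replicate artefacts,
diploid genomes, and trended dispersion in expression counts. Passing
recovery tests on these simulations therefore demonstrates the
correctness and calibration of the computations, not performance on any
particular real data set.

# Pipeline, seeds and determinism

`runPipeline()` executes the stages from a validated YAML config
(`validateConfig()`: defaults filled, unknown keys rejected, ranges
checked) and writes all artifacts plus a JSON report;
`runSyntheticBenchmark()` is the one-command in-memory benchmark. A single
global seed deterministically derives per-stage seeds by hashing the stage
name (`stageSeed()`), so any stage can be rerun in isolation and the full
report is byte-identical across runs. `genomeSeed` can be pinned
independently of `seed`: comparing conditions (e.g. enhancer-bias levels)
on one fixed genome is a paired design that removes genome-level variance
from the contrast, and the benchmark suite uses it for the bias-gradient
check.

Problem sizes used by the shipped tests — chosen to make every Monte-Carlo
bound tight enough to be meaningful while keeping the whole suite fast —
are 10^4–2×10^4 bins, 40–300 planted domains, 199–3000 permutations per
enrichment test, and 300–500 repeats for calibration fractions.

# Numerical choices and degenerate inputs

* Zero pooled variance in a bin: variance floored at 10^-12; if the means
  are also equal, t = 0 and p = 1. Only degenerate inputs reach this.
* Two-sided p values with a post-hoc direction filter; the up direction is
  the default output (the biology of interest is signal gain), down and
  both are available.
* `bhAdjust()` validates the input range and otherwise defers to
  `stats::p.adjust(method = "BH")`; an independent brute-force step-up
  implementation lives in the test suite as its oracle. The protocol text
  we follow names the correction ambiguously ("Bonferroni-Hochberg"); we
  read it as Benjamini–Hochberg, with plain Bonferroni available in
  `deTest()`.
* Chromosome-terminal bins are truncated, retained, and averaged over
  their true width; a denylist overlap of ≥1 bp removes a bin entirely.
* Empty query sets skip the enrichment test with a message; an annotation
  that misses the workspace gives expected overlap 0 and an NA fold with a
  warning rather than an Inf.
* bedGraph is the canonical round-trip track format (byte-stable integer
  formatting); bigWig is supported read-only through `rtracklayer`.

# Known limitations

* The per-bin Student's t with few replicates has the power ceiling
  described above; moderate effect sizes require more replicates or a
  shrinkage/NB framework (edgeR, limma), which can be plugged into the
  classification stage but intentionally not into the domain caller,
  whose per-bin test is the procedure under study.
* The permutation sampler conditions only on the workspace; G+C- or
  isochore-matched nulls are not implemented.
* Domains are merged, never split; adjacent distinct true domains closer
  than one bin merge into one call.
* Enrichment is measured in base pairs, not segment counts.
* Down-regulated genes are reported by `deTest()` but not classified
  further.
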