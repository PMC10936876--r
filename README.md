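# epidomains

Linking stimulus-induced chromatin changes to gene regulation, at desk
scale and with ground truth.

When a growth factor activates a nuclear kinase that deposits a histone
mark (for example the phospho-methyl mark H3K9me2S10ph) at specific
genomic sites, three computational questions follow:

1. **Where does the mark increase?** From replicate CUT&RUN coverage
   tracks of two conditions plus an IgG background track, call the
   genomic domains with significantly higher signal after stimulation.
2. **Are those domains where regulation happens?** Test whether the
   domains overlap enhancers of stimulus-responsive genes more than
   expected by chance.
3. **Which responsive genes need the kinase?** From a three-condition
   expression matrix (control, stimulated, stimulated + kinase
   knockdown), split stimulation-up-regulated genes into
   knockdown-dependent and -independent sets — the gene sets the
   enrichment test then uses as enhancer categories.

`epidomains` implements all three stages as composable Bioconductor-style
functions, plus a synthetic-data module that generates miniature genomes,
coverage tracks with planted differential domains, and expression counts
with planted kinase-dependent genes — so every statistical claim the
package makes is checked against known truth in its test suite.

## The statistics

**Domain calling.** The genome is tiled into 1-kb bins; per-sample bin
signal is CPM-normalised, IgG-subtracted, denylist-filtered, z-scored per
sample, and smoothed with centred rolling windows of 10 bins. Each bin
gets an equal-variance Student's *t* test across replicates
(treated vs control), two-sided *p* values are Benjamini–Hochberg
adjusted, and book-ended bins with adjusted *p* < 0.005 merge into
domains.

**Interval enrichment.** For called domains *D*, annotation category *A*
and mappable workspace *W*, the fold enrichment is

    fold = observed / expected,   observed = |D ∩ A| (bp),
    expected = mean over simulations of |D* ∩ A|

where each simulated *D\** re-places every domain independently and
length-preserved, uniformly over all legal positions within *W* (interval
chosen proportional to its count of valid starts). Empirical *p* values
use the +1/+1 correction: at 1000 simulations the smallest attainable
*p* is 1/1001.

**Dependence classification.** Genes with CPM > 10 in ≥ 2 samples are
tested (Welch's *t* on log2(CPM+1) by default; external edgeR-style tables
plug in); up-regulation requires log fold change > 0.5 and adjusted
*p* < 0.05. Up genes are hierarchically clustered on row-scaled
per-condition means across the three conditions; in the cluster with the
largest treated-minus-knockdown profile difference, genes significantly
lower under knockdown are *dependent*, the rest *independent*.

## Worked example

```r
library(epidomains)

bench <- runSyntheticBenchmark(seed = 1, nBins = 10000, nDomains = 75,
                               effect = 8, enhancerBias = 4, nSim = 1000)
r <- bench$report
r$domains$n_domains        # 78 domains called at adjusted p < 0.005
r$recovery$sensitivity     # 0.787  (planted domains found, +-5 kb)
r$recovery$precision       # 0.949  (called domains near a planted one)
r$enrichment[, c("category", "fold", "p_enrich")]
```

```
                  category      fold   p_enrich
1            all_enhancers 1.3107923 0.06893107
2                promoters 1.2067614 0.19180819
3              gene_bodies 0.9766094 0.53546454
4  enhancers_of_responsive 2.1449342 0.01498501
5   enhancers_of_dependent 1.5855701 0.26473526
6 enhancers_of_independent 2.4126129 0.01698302
```

Domains were planted with an 8-fold treated-condition effect and a 4-fold
placement bias towards enhancers of responsive genes. The caller recovers
79% of planted domains with 95% precision (localisation is limited to
half a smoothing window — see `domainRecovery()`), and the enrichment
stage sees what was planted: enhancers of responsive genes are ~2-fold
enriched over random placement while gene bodies sit at fold ≈ 1. The
`gene_sets` element records the classifier's outputs (here 57 responsive
genes, of which 14 knockdown-dependent) that defined those categories.

The same stages run from files: `runPipeline(validateConfig("cfg.yaml"))`
consumes bedGraph/bigWig tracks, BED annotations and a counts TSV, and
writes domains (BED), per-bin statistics and enrichment tables (TSV),
gene sets, and a JSON report. `inst/scripts/epidomains.R` wraps
`simulate` and `run` for the shell.

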