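Package: epidomains
Title: Differential Histone-Mark Domain Calling and Permutation-Based
    Enhancer Enrichment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking stimulus-induced chromatin-mark changes to
    gene regulation from binned coverage tracks. Implements a replicate-aware
    differential-signal domain caller for broad histone modifications
    (counts-per-million normalisation, IgG background subtraction, denylist
    filtering, per-sample z-scoring, rolling-window smoothing, per-bin
    Student's t tests with Benjamini-Hochberg correction, and merging of
    book-ended significant bins into domains), a permutation-based genomic
    interval enrichment test of observed versus expected base-pair overlap
    within a mappable workspace, and a three-condition expression classifier
    that splits stimulus-up-regulated genes into kinase-knockdown-dependent
    and -independent sets. A synthetic-data module generates miniature
    genomes, coverage tracks with planted differential domains, and
    negative-binomial expression counts with planted responsive genes, with
    recorded ground truth for recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
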