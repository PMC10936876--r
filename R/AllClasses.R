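#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   reduce findOverlaps countOverlaps strand resize trim promoters
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo
#'   keepSeqlevels seqlengths<-
#' @importFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment assay assays rowRanges colData colData<-
NULL

.STAGES <- c("raw", "cpm", "ctrl_subtracted", "zscore", "smoothed")

#' Genome layout for binned analyses
#'
#' Holds chromosome names and lengths together with the bin width used to
#' tile the genome into fixed windows (1 kb by default, the resolution at
#' which broad-mark coverage is analysed).
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot binSize Integer bin width in base pairs.
#'
#' @examples
#' layout <- GenomeLayout(c(chr1 = 50000, chr2 = 20000), binSize = 1000)
#' binSize(layout)
#' @export
setClass("GenomeLayout",
    representation(seqinfo = "Seqinfo", binSize = "integer"))

setValidity("GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    if (length(sl) < 1L) return("at least one chromosome is required")
    if (anyNA(sl) || any(sl <= 0)) return("chromosome lengths must be > 0")
    if (anyDuplicated(seqlevels(object@seqinfo)))
        return("chromosome names must be unique")
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize <= 0L)
        return("binSize must be a single positive integer")
    TRUE
})

#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param binSize Bin width in base pairs.
#' @rdname GenomeLayout-class
#' @export
GenomeLayout <- function(chromLengths, binSize = 1000L) {
    if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
        stop("'chromLengths' must be a named vector")
    si <- Seqinfo(seqnames = names(chromLengths),
                  seqlengths = as.integer(chromLengths))
    new("GenomeLayout", seqinfo = si, binSize = as.integer(binSize))
}

#' Annotation bundle for a (synthetic or real) genome
#'
#' Groups the interval annotations the pipeline consumes: enhancers carrying
#' linked gene identifiers (comma-separated in `mcols()$gene_id`, so an
#' enhancer may serve several genes), promoters and gene bodies with gene
#' identifiers, a denylist of artifact-prone regions excluded from analysis,
#' and the mappable workspace within which permutations are confined.
#'
#' @slot enhancers,promoters,geneBodies,denylist,workspace [GenomicRanges::GRanges].
#' @export
setClass("AnnotationBundle",
    representation(enhancers = "GRanges", promoters = "GRanges",
                   geneBodies = "GRanges", denylist = "GRanges",
                   workspace = "GRanges"))

setValidity("AnnotationBundle", function(object) {
    if (length(GenomicRanges::intersect(object@workspace, object@denylist,
                                        ignore.strand = TRUE)) > 0L)
        return("workspace and denylist must be disjoint")
    for (nm in c("enhancers", "promoters", "geneBodies")) {
        gr <- slot(object, nm)
        sl <- seqlengths(gr)
        if (!anyNA(sl) && length(gr) &&
            any(end(gr) > sl[as.character(seqnames(gr))]))
            return(sprintf("'%s' extend past chromosome ends", nm))
    }
    TRUE
})

#' @param enhancers,promoters,geneBodies,denylist,workspace `GRanges`.
#' @rdname AnnotationBundle-class
#' @export
AnnotationBundle <- function(enhancers, promoters, geneBodies, denylist,
                             workspace) {
    new("AnnotationBundle", enhancers = enhancers, promoters = promoters,
        geneBodies = geneBodies, denylist = denylist, workspace = workspace)
}

#' Ground truth of a synthetic simulation
#'
#' Records what was planted so recovery can be scored: differential-signal
#' domains with their effect multiplier on the treated-condition mean,
#' the enhancer placement bias used, and the responsive / knockdown-dependent
#' gene sets.
#'
#' @slot plantedDomains `GRanges` with an `effect` metadata column (fold
#'   increase of the treated mean inside the domain; >= 1).
#' @slot enhancerBias Numeric placement weight for bins at enhancers of
#'   responsive genes relative to the rest of the workspace (1 = uniform).
#' @slot responsiveGenes,dependentGenes Character gene identifiers;
#'   `dependentGenes` is a subset of `responsiveGenes`.
#' @slot seeds Integer seeds used by the generators.
#' @export
setClass("SimulationTruth",
    representation(plantedDomains = "GRanges", enhancerBias = "numeric",
                   responsiveGenes = "character",
                   dependentGenes = "character", seeds = "integer"))

setValidity("SimulationTruth", function(object) {
    if (!all(object@dependentGenes %in% object@responsiveGenes))
        return("dependentGenes must be a subset of responsiveGenes")
    eff <- mcols(object@plantedDomains)$effect
    if (length(object@plantedDomains) &&
        (is.null(eff) || any(eff < 1)))
        return("planted domains need an 'effect' column with values >= 1")
    TRUE
})

#' Binned signal matrix
#'
#' A bins-by-samples matrix of coverage-derived values, carried through the
#' normalisation pipeline as a [SummarizedExperiment::RangedSummarizedExperiment]
#' with one extra piece of state: the processing `stage`, one of
#' `"raw"`, `"cpm"`, `"ctrl_subtracted"`, `"zscore"`, `"smoothed"`.
#' Stage transitions are only allowed in that order; each pipeline step
#' checks the stage of its input so mis-ordered pipelines fail loudly.
#' `colData` holds the sample sheet (`sample_id`, `condition`, `replicate`,
#' `role`), `rowRanges` the (sorted, fixed-width apart from chromosome-terminal)
#' bins.
#'
#' @slot stage Character scalar; the current processing stage.
#' @export
setClass("BinnedSignal", contains = "RangedSummarizedExperiment",
    representation(stage = "character"))

setValidity("BinnedSignal", function(object) {
    if (length(object@stage) != 1L || !object@stage %in% .STAGES)
        return(sprintf("stage must be one of: %s",
                       paste(.STAGES, collapse = ", ")))
    cd <- colData(object)
    need <- c("sample_id", "condition", "replicate", "role")
    if (!all(need %in% colnames(cd)))
        return(sprintf("colData must contain: %s", paste(need, collapse = ", ")))
    gr <- rowRanges(object)
    if (length(gr) > 1L) {
        o <- order(as.integer(seqnames(gr)), start(gr))
        if (!identical(o, seq_along(gr)))
            return("bins must be sorted by (chromosome, start)")
    }
    TRUE
})

#' @param values Numeric matrix, bins x samples.
#' @param bins `GRanges` of bins (sorted by chromosome then start).
#' @param sampleSheet `data.frame`/`DataFrame` with columns `sample_id`,
#'   `condition`, `replicate`, `role` (`"target"` or `"igg_control"`).
#' @param stage Processing stage label.
#' @rdname BinnedSignal-class
#' @export
BinnedSignal <- function(values, bins, sampleSheet, stage = "raw") {
    sampleSheet <- DataFrame(sampleSheet)
    colnames(values) <- sampleSheet$sample_id
    se <- SummarizedExperiment(assays = list(values = as.matrix(values)),
                               rowRanges = bins, colData = sampleSheet)
    new("BinnedSignal", se, stage = stage)
}

#' Result of a differential-domain call
#'
#' Bundles per-bin statistics (mean smoothed-score difference, t statistic,
#' two-sided p, BH-adjusted p, direction) with the merged significant
#' domains and their summary.
#'
#' @slot binStats `DataFrame`, one row per bin.
#' @slot bins `GRanges` the statistics refer to.
#' @slot domains `GRanges` of merged significant bins, with `direction` and
#'   `score` (-log10 of the minimum adjusted p among member bins).
#' @slot alpha Adjusted-p threshold used.
#' @slot direction `"up"`, `"down"` or `"both"`.
#' @slot summary List with `n_domains`, `mean_length_bp`, `genome_fraction`
#'   (filled by [summarizeDomains()]).
#' @export
setClass("DomainCallResult",
    representation(binStats = "DataFrame", bins = "GRanges",
                   domains = "GRanges", alpha = "numeric",
                   direction = "character", summary = "list"))

setValidity("DomainCallResult", function(object) {
    if (nrow(object@binStats) != length(object@bins))
        return("binStats and bins must have matching length")
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        return("alpha must be in (0, 1)")
    d <- object@domains
    if (length(d) > 1L) {
        o <- order(as.integer(seqnames(d)), start(d))
        if (!identical(o, seq_along(d)))
            return("domains must be sorted")
        same <- as.character(seqnames(d))[-length(d)] ==
            as.character(seqnames(d))[-1]
        if (any(same & start(d)[-1] < end(d)[-length(d)] &
                mcols(d)$direction[-length(d)] == mcols(d)$direction[-1]))
            return("same-direction domains must not overlap")
    }
    TRUE
})

#' Result of a permutation interval-enrichment test
#'
#' Observed base-pair overlap of a query interval set with an annotation,
#' the null distribution of that overlap under random length-preserving
#' placement within the workspace, the observed/expected fold, and empirical
#' enrichment/depletion p values (with the +1/+1 correction, so p is never
#' zero: the smallest attainable p at 1000 simulations is 1/1001).
#'
#' @slot category Annotation name.
#' @slot observed Observed overlap (bp).
#' @slot expected Mean overlap (bp) over simulations.
#' @slot expectedDist Numeric vector of simulated overlaps.
#' @slot fold observed/expected (NA when expected is 0).
#' @slot pEnrich,pDeplete Empirical p values.
#' @slot nSim Number of simulations.
#' @slot seed Seed used (NA when placements were drawn from the current
#'   RNG state).
#' @export
setClass("EnrichmentResult",
    representation(category = "character", observed = "numeric",
                   expected = "numeric", expectedDist = "numeric",
                   fold = "numeric", pEnrich = "numeric",
                   pDeplete = "numeric", nSim = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
    p <- c(object@pEnrich, object@pDeplete)
    if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
        return("empirical p values must lie in (0, 1]")
    if (!is.na(object@fold) && object@fold < 0)
        return("fold must be >= 0")
    TRUE
})
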