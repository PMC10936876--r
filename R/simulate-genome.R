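#' Simulate a miniature annotated genome
#'
#' Generates a small multi-chromosome genome with non-overlapping gene
#' bodies, TSS-derived promoters, distal enhancers linked to genes, a sparse
#' denylist of excluded regions, and the mappable workspace (chromosomes
#' minus denylist). Used as the substrate for coverage and expression
#' simulations with known ground truth.
#'
#' Gene bodies are placed one per equally sized block along each chromosome
#' (at a random offset within the block), which guarantees they never
#' overlap. Enhancers are placed around each gene's TSS at a uniform offset
#' up to `enhancerMaxDist`; their `gene_id` metadata column carries the
#' linked gene (comma-separated when an enhancer serves several genes).
#' Promoters span `promoterUpstream` bp upstream to `promoterDownstream` bp
#' downstream of the TSS, strand-aware.
#'
#' @param chromLengths Named vector of chromosome lengths in bp, or a single
#'   unnamed length used for `nChrom` chromosomes named `chr1..chrN`.
#' @param nChrom Number of chromosomes when `chromLengths` is scalar.
#' @param nGenes Total number of genes (>= 0).
#' @param geneLength Gene body length in bp.
#' @param enhancersPerGene Enhancers linked to each gene.
#' @param enhancerLength Enhancer width in bp.
#' @param enhancerMaxDist Maximum |TSS - enhancer centre| distance in bp.
#' @param denylistFraction Fraction of the genome covered by denylist
#'   intervals (approximate, before merging).
#' @param denylistMeanLength Mean denylist interval length in bp.
#' @param binSize Bin width recorded in the returned layout.
#' @param promoterUpstream,promoterDownstream Promoter extent around the TSS.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list with elements `layout` ([GenomeLayout]), `annotation`
#'   ([AnnotationBundle]) and `genes` (a `data.frame` with `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`).
#' @examples
#' g <- simulateGenome(chromLengths = 2e5, nChrom = 1, nGenes = 10, seed = 1)
#' g$annotation
#' @export
simulateGenome <- function(chromLengths = 5e6, nChrom = 2L, nGenes = 300L,
                           geneLength = 5000L, enhancersPerGene = 2L,
                           enhancerLength = 1000L, enhancerMaxDist = 50000L,
                           denylistFraction = 0.01,
                           denylistMeanLength = 3000L, binSize = 1000L,
                           promoterUpstream = 1000L,
                           promoterDownstream = 500L, seed = 1L) {
    if (is.null(names(chromLengths))) {
        if (length(chromLengths) == 1L)
            chromLengths <- rep(chromLengths, nChrom)
        names(chromLengths) <- paste0("chr", seq_along(chromLengths))
    }
    layout <- GenomeLayout(chromLengths, binSize = binSize)
    si <- layout@seqinfo
    totalLen <- sum(as.numeric(chromLengths))
    if (nGenes * geneLength > 0.5 * totalLen)
        stop("requested annotation length exceeds half the genome; ",
             "reduce 'nGenes' or 'geneLength'")
    .assertScalar(denylistFraction, "denylistFraction", 0, 0.5)
    set.seed(stageSeed(seed, "genome"))

    genes <- .placeGenes(chromLengths, nGenes, geneLength)
    geneGR <- if (nrow(genes)) {
        GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end),
                strand = genes$strand, gene_id = genes$gene_id,
                seqinfo = si)
    } else GRanges(seqinfo = si)

    prom <- if (length(geneGR)) {
        p <- suppressWarnings(promoters(geneGR, upstream = promoterUpstream,
                                        downstream = promoterDownstream))
        trim(p)
    } else GRanges(seqinfo = si)

    enh <- .placeEnhancers(genes, chromLengths, enhancersPerGene,
                           enhancerLength, enhancerMaxDist, si)

    deny <- .drawDenylist(chromLengths, denylistFraction,
                          denylistMeanLength, si)
    genome <- GRanges(names(chromLengths),
                      IRanges(1L, as.integer(chromLengths)), seqinfo = si)
    ws <- GenomicRanges::setdiff(genome, deny, ignore.strand = TRUE)

    ann <- AnnotationBundle(enhancers = enh, promoters = prom,
                            geneBodies = geneGR, denylist = deny,
                            workspace = ws)
    list(layout = layout, annotation = ann, genes = genes)
}

.placeGenes <- function(chromLengths, nGenes, geneLength) {
    if (nGenes < 1L)
        return(data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), tss = integer()))
    # allocate genes to chromosomes proportionally to length
    alloc <- floor(nGenes * chromLengths / sum(chromLengths))
    rem <- nGenes - sum(alloc)
    if (rem > 0)
        alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    out <- vector("list", length(chromLengths))
    idx0 <- 0L
    for (ci in seq_along(chromLengths)) {
        ng <- alloc[ci]
        if (ng < 1L) { out[[ci]] <- NULL; next }
        L <- chromLengths[ci]
        block <- floor(L / ng)
        if (block <= geneLength)
            stop("gene bodies do not fit: reduce 'nGenes' or 'geneLength'")
        offset <- floor(stats::runif(ng) * (block - geneLength))
        start <- (seq_len(ng) - 1L) * block + offset      # 0-based
        strand <- sample(c("+", "-"), ng, replace = TRUE)
        out[[ci]] <- data.frame(
            gene_id = sprintf("g%04d", idx0 + seq_len(ng)),
            chrom = names(chromLengths)[ci],
            start = as.integer(start),
            end = as.integer(start + geneLength),
            strand = strand,
            tss = as.integer(ifelse(strand == "+", start,
                                    start + geneLength)))
        idx0 <- idx0 + ng
    }
    do.call(rbind, out)
}

.placeEnhancers <- function(genes, chromLengths, perGene, width, maxDist,
                            si) {
    if (nrow(genes) < 1L || perGene < 1L)
        return(GRanges(seqinfo = si))
    n <- nrow(genes) * perGene
    gi <- rep(seq_len(nrow(genes)), each = perGene)
    offset <- floor(stats::runif(n, -maxDist, maxDist))
    centre <- genes$tss[gi] + offset
    start0 <- centre - floor(width / 2)               # 0-based
    L <- chromLengths[genes$chrom[gi]]
    start0 <- pmin(pmax(start0, 0), L - width)
    GRanges(genes$chrom[gi], IRanges(start0 + 1L, start0 + width),
            gene_id = genes$gene_id[gi], seqinfo = si)
}

.drawDenylist <- function(chromLengths, fraction, meanLength, si) {
    totalLen <- sum(as.numeric(chromLengths))
    nIntervals <- round(totalLen * fraction / meanLength)
    if (fraction <= 0 || nIntervals < 1L)
        return(GRanges(seqinfo = si))
    chromIdx <- sample(seq_along(chromLengths), nIntervals, replace = TRUE,
                       prob = chromLengths)
    len <- floor(stats::runif(nIntervals, 0.5 * meanLength,
                              1.5 * meanLength))
    start0 <- floor(stats::runif(nIntervals) *
                        (chromLengths[chromIdx] - len))
    gr <- GRanges(names(chromLengths)[chromIdx],
                  IRanges(start0 + 1L, start0 + len), seqinfo = si)
    reduce(.sortGR(gr))
}

#' Plant differential-signal domains and responsive gene sets
#'
#' Chooses ground-truth domain locations (aligned to bin boundaries) and the
#' responsive / knockdown-dependent gene sets for a simulation. Domain start
#' bins are drawn from the denylist-free workspace; bins overlapping an
#' enhancer of a responsive gene receive placement weight `enhancerBias`
#' relative to weight 1 elsewhere, so `enhancerBias = 1` gives uniform
#' placement and larger values concentrate domains at responsive-gene
#' enhancers — the structure the downstream enrichment test is meant to
#' detect. Placed domains are kept at least `minGapBins` bins apart so they
#' remain distinct after merging and smoothing.
#'
#' @param layout A [GenomeLayout].
#' @param annotation An [AnnotationBundle].
#' @param genes Gene table from [simulateGenome()].
#' @param nDomains Number of domains to plant.
#' @param domainLengthBins Integer vector of candidate domain lengths in
#'   bins; each domain's length is drawn uniformly from it.
#' @param effect Fold increase (>= 1) of the treated-condition mean signal
#'   inside a domain; scalar or one value per domain.
#' @param enhancerBias Placement weight (>= 0) for responsive-enhancer bins.
#' @param responsiveFraction Fraction of genes planted as responsive.
#' @param dependentFraction Fraction of responsive genes whose induction is
#'   abolished under knockdown.
#' @param minGapBins Minimum gap between planted domains, in bins.
#' @param seed Integer seed.
#' @return A [SimulationTruth].
#' @examples
#' g <- simulateGenome(2e5, nChrom = 1, nGenes = 20, seed = 1)
#' tr <- plantTruth(g$layout, g$annotation, g$genes, nDomains = 5, seed = 1)
#' plantedDomains(tr)
#' @export
plantTruth <- function(layout, annotation, genes, nDomains = 75L,
                       domainLengthBins = c(1L, 2L), effect = 6,
                       enhancerBias = 1, responsiveFraction = 0.2,
                       dependentFraction = 0.25, minGapBins = 10L,
                       seed = 1L) {
    .assertScalar(enhancerBias, "enhancerBias", 0)
    .assertScalar(responsiveFraction, "responsiveFraction", 0, 1)
    .assertScalar(dependentFraction, "dependentFraction", 0, 1)
    if (any(effect < 1)) stop("'effect' multipliers must be >= 1")
    set.seed(stageSeed(seed, "truth"))

    allGenes <- genes$gene_id
    responsive <- sort(sample(allGenes,
                              round(responsiveFraction * length(allGenes))))
    dependent <- sort(sample(responsive,
                             round(dependentFraction * length(responsive))))

    bins <- makeBins(layout)
    candidate <- !overlapsAny(bins, denylist(annotation))
    respEnh <- enhancers(annotation)
    if (length(respEnh)) {
        linked <- vapply(.splitGeneIds(mcols(respEnh)$gene_id),
                         function(g) any(g %in% responsive), logical(1))
        respEnh <- respEnh[linked]
    }
    w <- rep(1, length(bins))
    w[overlapsAny(bins, respEnh)] <- enhancerBias
    w[!candidate] <- 0

    chromIdx <- as.integer(seqnames(bins))
    lens <- sample(rep(domainLengthBins, length.out = nDomains))
    avail <- candidate
    startBin <- integer(nDomains)
    for (d in seq_len(nDomains)) {
        l <- lens[d]
        ok <- avail & w > 0
        if (l > 1L) {
            for (k in seq_len(l - 1L)) {
                nxt <- c(avail[-seq_len(k)], rep(FALSE, k)) &
                    c(chromIdx[-seq_len(k)], rep(NA, k)) == chromIdx
                ok <- ok & !is.na(nxt) & nxt
            }
        }
        if (!any(ok))
            stop("requested domains cannot be placed within the workspace; ",
                 "reduce 'nDomains' or 'minGapBins'")
        okIdx <- which(ok)
        s <- okIdx[sample.int(length(okIdx), 1L, prob = w[okIdx])]
        startBin[d] <- s
        lo <- max(1L, s - minGapBins)
        hi <- min(length(bins), s + l - 1L + minGapBins)
        avail[lo:hi] <- FALSE
    }
    dom <- GRanges(seqnames(bins)[startBin],
                   IRanges(start(bins)[startBin],
                           end(bins)[pmin(startBin + lens - 1L,
                                          length(bins))]),
                   seqinfo = layout@seqinfo)
    mcols(dom)$effect <- rep(effect, length.out = nDomains)
    dom <- .sortGR(dom)
    new("SimulationTruth", plantedDomains = dom,
        enhancerBias = enhancerBias, responsiveGenes = responsive,
        dependentGenes = dependent, seeds = as.integer(seed))
}

#' Effect multiplier for a target shift in within-replicate standard
#' deviations
#'
#' Converts an effect expressed as a number of per-bin count standard
#' deviations into the multiplicative fold on the treated mean that
#' [simulateCoverage()] applies, given the baseline and IgG rates and the
#' noise model. For Poisson noise the per-bin variance of the
#' control-subtracted signal is `baselineRate + iggRate`; negative-binomial
#' noise adds `dispersion * rate^2` per track.
#'
#' @param sdUnits Desired shift in within-replicate standard deviations.
#' @param baselineRate Mean per-bin count of the target tracks.
#' @param iggRate Mean per-bin count of the IgG control tracks.
#' @param dispersion Negative-binomial dispersion (0 for Poisson).
#' @return Effect multiplier (>= 1) for [plantTruth()].
#' @examples
#' effectFromSd(2, baselineRate = 25, iggRate = 2)
#' @export
effectFromSd <- function(sdUnits, baselineRate, iggRate = 0,
                         dispersion = 0) {
    .assertScalar(sdUnits, "sdUnits", 0)
    .assertScalar(baselineRate, "baselineRate", 0, openLower = TRUE)
    v <- baselineRate + dispersion * baselineRate^2 +
        iggRate + dispersion * iggRate^2
    1 + sdUnits * sqrt(v) / baselineRate
}
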