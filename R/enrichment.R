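#' Base pairs of overlap between two interval sets
#'
#' Total base pairs in the intersection of two genomic interval sets,
#' strand-ignorant.
#'
#' @param query,annotation `GRanges`.
#' @return A single number of base pairs.
#' @examples
#' overlapWidth(GenomicRanges::GRanges("chr1:1-100"),
#'              GenomicRanges::GRanges("chr1:51-150"))
#' @export
overlapWidth <- function(query, annotation) {
    sum(as.numeric(width(GenomicRanges::intersect(query, annotation,
                                                  ignore.strand = TRUE))))
}

# Global-coordinate machinery: map every chromosome to a disjoint block of
# a single axis so one findInterval serves all chromosomes. Positions are
# 0-based within chromosome.
.globalCoords <- function(workspace) {
    lev <- seqlevels(workspace)
    sl <- seqlengths(workspace)
    if (anyNA(sl)) {
        ends <- vapply(lev, function(l) {
            w <- workspace[seqnames(workspace) == l]
            if (length(w)) max(end(w)) else 0L
        }, numeric(1))
        sl[is.na(sl)] <- ends[is.na(sl)]
    }
    offset <- c(0, cumsum(as.numeric(sl)))[seq_along(lev)]
    names(offset) <- lev
    offset
}

# merged annotation as global 0-based [start, end) arrays + covered-bp prefix
.prepAnnotation <- function(annotation, offset) {
    ann <- reduce(.sortGR(GenomicRanges::granges(annotation)),
                  ignore.strand = TRUE)
    s <- offset[as.character(seqnames(ann))] + start(ann) - 1
    e <- offset[as.character(seqnames(ann))] + end(ann)
    o <- order(s)
    list(start = s[o], end = e[o],
         cumBefore = c(0, cumsum(e[o] - s[o]))[seq_along(s)])
}

# covered annotation bp in [0, pos) (global 0-based positions)
.coveredBefore <- function(prep, pos) {
    if (length(prep$start) == 0L) return(numeric(length(pos)))
    idx <- findInterval(pos, prep$start)
    out <- numeric(length(pos))
    hit <- idx > 0L
    out[hit] <- prep$cumBefore[idx[hit]] +
        pmax(0, pmin(pos[hit], prep$end[idx[hit]]) - prep$start[idx[hit]])
    out
}

# workspace as a table of intervals in global coordinates
.prepWorkspace <- function(workspace, offset) {
    ws <- reduce(.sortGR(GenomicRanges::granges(workspace)),
                 ignore.strand = TRUE)
    data.frame(start = offset[as.character(seqnames(ws))] + start(ws) - 1,
               width = as.numeric(width(ws)))
}

# draw n placements for segments of one length L; returns global starts
.drawStarts <- function(wsTab, L, n) {
    valid <- pmax(wsTab$width - L + 1, 0)
    if (all(valid == 0))
        stop("a segment of length ", L,
             " is longer than every workspace interval")
    idx <- sample.int(nrow(wsTab), n, replace = TRUE, prob = valid)
    wsTab$start[idx] + floor(stats::runif(n) * valid[idx])
}

#' Randomly re-place query segments within a workspace
#'
#' Produces one random placement per query segment: segment lengths are
#' preserved, every placement falls entirely within a single workspace
#' interval, and the interval is chosen with probability proportional to
#' its number of valid start positions (interval width - segment length
#' + 1), so placement is exactly uniform over all legal positions.
#' Placements are independent; mutual overlap is allowed.
#'
#' Draws use the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param query `GRanges` of segments to re-place.
#' @param workspace `GRanges` of the mappable genome.
#' @return A `GRanges` with one placement per query segment (lengths
#'   preserved, order by segment length groups).
#' @export
permuteSegments <- function(query, workspace) {
    offset <- .globalCoords(workspace)
    wsTab <- .prepWorkspace(workspace, offset)
    lens <- width(query)
    starts <- numeric(0)
    outLen <- integer(0)
    for (L in sort(unique(lens))) {
        n <- sum(lens == L)
        starts <- c(starts, .drawStarts(wsTab, L, n))
        outLen <- c(outLen, rep(L, n))
    }
    .fromGlobal(starts, outLen, workspace, offset)
}

.fromGlobal <- function(starts, lens, workspace, offset) {
    lev <- seqlevels(workspace)
    bounds <- c(offset, sum(as.numeric(seqlengths(workspace)), na.rm = TRUE) +
                    .Machine$double.eps)
    chromIdx <- findInterval(starts, offset)
    GRanges(lev[chromIdx],
            IRanges(start = starts - offset[chromIdx] + 1,
                    width = lens),
            seqinfo = seqinfo(workspace))
}

#' Permutation test of interval overlap enrichment
#'
#' Tests whether a query interval set overlaps an annotation more (or less)
#' than expected by chance, by comparing the observed base-pair overlap to
#' its distribution over `nSim` random length-preserving placements of the
#' query segments within the mappable workspace. The fold enrichment is
#' the ratio of observed over expected (the simulation mean); empirical p
#' values use the +1/+1 correction, so the smallest attainable p at 1000
#' simulations is 1/1001.
#'
#' @param query `GRanges`; the intervals under test (e.g. called domains),
#'   assumed to lie within the workspace.
#' @param annotation `GRanges`; the category to test against (clipped to
#'   the workspace internally).
#' @param workspace `GRanges` of the mappable genome.
#' @param nSim Number of simulations (default 1000).
#' @param seed Optional integer seed for the placements.
#' @param category Name recorded in the result.
#' @return An [EnrichmentResult].
#' @examples
#' ws <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
#' ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000))
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2501, 2700))
#' enrichmentTest(q, ann, ws, nSim = 200, seed = 1)
#' @export
enrichmentTest <- function(query, annotation, workspace, nSim = 1000L,
                           seed = NULL, category = NA_character_) {
    nSim <- as.integer(nSim)
    if (nSim < 1L) stop("'nSim' must be >= 1")
    if (length(query) == 0L) {
        message("empty query: enrichment test skipped")
        return(new("EnrichmentResult", category = category, observed = 0,
                   expected = NA_real_, expectedDist = numeric(0),
                   fold = NA_real_, pEnrich = NA_real_,
                   pDeplete = NA_real_, nSim = 0L,
                   seed = if (is.null(seed)) NA_integer_
                          else as.integer(seed)))
    }
    if (!is.null(seed)) set.seed(as.integer(seed))
    annotation <- GenomicRanges::intersect(annotation, workspace,
                                           ignore.strand = TRUE)
    observed <- overlapWidth(query, annotation)

    offset <- .globalCoords(workspace)
    wsTab <- .prepWorkspace(workspace, offset)
    prep <- .prepAnnotation(annotation, offset)
    lens <- width(query)
    simTot <- numeric(nSim)
    for (L in sort(unique(lens))) {
        cnt <- sum(lens == L)
        s <- .drawStarts(wsTab, L, nSim * cnt)
        ov <- .coveredBefore(prep, s + L) - .coveredBefore(prep, s)
        simTot <- simTot + rowSums(matrix(ov, nrow = nSim))
    }
    expected <- mean(simTot)
    fold <- if (expected > 0) observed / expected else NA_real_
    if (is.na(fold))
        warning("expected overlap is 0 (annotation misses the workspace); ",
                "fold is undefined")
    new("EnrichmentResult", category = category, observed = observed,
        expected = expected, expectedDist = simTot, fold = fold,
        pEnrich = (1 + sum(simTot >= observed)) / (1 + nSim),
        pDeplete = (1 + sum(simTot <= observed)) / (1 + nSim),
        nSim = nSim,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Build annotation categories for enrichment testing
#'
#' Assembles the named interval categories the enrichment stage tests
#' against: all enhancers, promoters, gene bodies, and — for every supplied
#' gene set — the merged union of enhancers linked to any gene in the set
#' (`enhancers_of_<name>`). Every category is strand-stripped, merged and
#' clipped to the workspace.
#'
#' @param annotation An [AnnotationBundle].
#' @param geneSets Named list of character vectors of gene identifiers.
#' @return A named `GRangesList` of categories.
#' @export
buildCategories <- function(annotation, geneSets = list()) {
    ws <- workspace(annotation)
    clip <- function(gr) GenomicRanges::intersect(
        reduce(GenomicRanges::granges(gr), ignore.strand = TRUE), ws,
        ignore.strand = TRUE)
    enh <- enhancers(annotation)
    out <- list(all_enhancers = clip(enh),
                promoters = clip(promoterRegions(annotation)),
                gene_bodies = clip(geneBodies(annotation)))
    known <- unique(mcols(geneBodies(annotation))$gene_id)
    links <- .splitGeneIds(mcols(enh)$gene_id)
    for (nm in names(geneSets)) {
        ids <- geneSets[[nm]]
        unknown <- setdiff(ids, known)
        if (length(unknown))
            warning(sprintf("gene set '%s': %d unknown id(s) skipped",
                            nm, length(unknown)))
        ids <- intersect(ids, known)
        keep <- vapply(links, function(g) any(g %in% ids), logical(1))
        cat <- clip(enh[keep])
        if (length(cat) == 0L)
            warning(sprintf("category 'enhancers_of_%s' is empty", nm))
        out[[paste0("enhancers_of_", nm)]] <- cat
    }
    GRangesList(out)
}

#' Run the enrichment test over every category
#'
#' @param query `GRanges` (e.g. called domains).
#' @param categories Named `GRangesList`, as from [buildCategories()].
#' @param workspace `GRanges` of the mappable genome.
#' @param nSim Simulations per category.
#' @param seed Integer seed; each category uses a seed derived from it and
#'   the category name, so single categories can be rerun in isolation.
#' @return A `data.frame` with one row per category: `category`,
#'   `observed_bp`, `expected_bp`, `fold`, `p_enrich`, `p_deplete`,
#'   `n_sim`, `seed`.
#' @export
enrichCategories <- function(query, categories, workspace, nSim = 1000L,
                             seed = 1L) {
    rows <- lapply(names(categories), function(nm) {
        r <- enrichmentTest(query, categories[[nm]], workspace, nSim = nSim,
                            seed = stageSeed(seed, paste0("enrich_", nm)),
                            category = nm)
        data.frame(category = nm, observed_bp = r@observed,
                   expected_bp = r@expected, fold = r@fold,
                   p_enrich = r@pEnrich, p_deplete = r@pDeplete,
                   n_sim = r@nSim, seed = r@seed)
    })
    do.call(rbind, rows)
}
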