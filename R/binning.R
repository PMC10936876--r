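#' Tile a genome into fixed-width bins
#'
#' Produces the 1-kb (by default) tiling used throughout the analysis. Each
#' chromosome is covered by fixed-width bins in `[0, length)`; the terminal
#' bin is truncated at the chromosome end and retained.
#'
#' @param layout A [GenomeLayout].
#' @param binSize Bin width in bp; defaults to the layout's own.
#' @return A `GRanges` of bins, sorted by (chromosome, start).
#' @examples
#' makeBins(GenomeLayout(c(chr1 = 2500), binSize = 1000))
#' @export
makeBins <- function(layout, binSize = layout@binSize) {
    .assertScalar(binSize, "binSize", 1)
    tiles <- GenomicRanges::tileGenome(seqlengths(layout@seqinfo),
                                       tilewidth = as.integer(binSize),
                                       cut.last.tile.in.chrom = TRUE)
    tiles
}

.requireStage <- function(x, expected, op) {
    if (!stage(x) %in% expected)
        stop(sprintf("%s expects stage %s, got '%s' (pipeline order is %s)",
                     op, paste(sQuote(expected), collapse = " or "),
                     stage(x), paste(.STAGES, collapse = " -> ")),
             call. = FALSE)
    invisible(x)
}

#' Average a coverage track over bins
#'
#' Reads a bedGraph (or bigWig) track and computes, for every bin, the
#' coverage value averaged over the bin's bases; bases not covered by any
#' record count as zero. Records on chromosomes absent from the bins'
#' genome are skipped with a warning.
#'
#' @param file Path to a bedGraph or bigWig file.
#' @param bins `GRanges` of bins (with seqinfo), as from [makeBins()].
#' @return Numeric vector of per-bin means, one value per bin.
#' @examples
#' \dontrun{readCoverage("sample1.bedGraph", bins)}
#' @export
readCoverage <- function(file, bins) {
    gr <- if (grepl("\\.(bedgraph|bdg)$", tolower(file)))
        rtracklayer::import(file, format = "bedGraph")
    else rtracklayer::import(file)
    if (is.null(gr$score) || !is.numeric(gr$score))
        stop("track has no numeric 'score' values: ", file)
    known <- as.character(seqnames(gr)) %in% seqlevels(bins)
    if (!all(known)) {
        warning(sprintf("%d record(s) on unknown chromosomes skipped in %s",
                        sum(!known), file))
        gr <- gr[known]
    }
    gr <- keepSeqlevels(gr, seqlevels(bins), pruning.mode = "coarse")
    seqlengths(gr) <- seqlengths(bins)
    cov <- GenomicRanges::coverage(gr, weight = gr$score)
    binned <- GenomicRanges::binnedAverage(bins, cov, "score")
    mcols(binned)$score
}

#' Assemble a raw bins-by-samples matrix from coverage tracks
#'
#' @param files Character vector of track paths, one per sample sheet row.
#' @param bins `GRanges` of bins.
#' @param sampleSheet `data.frame` with columns `sample_id`, `condition`,
#'   `replicate`, `role`.
#' @return A [BinnedSignal] at stage `"raw"`.
#' @export
binCoverageMatrix <- function(files, bins, sampleSheet) {
    if (length(files) != nrow(sampleSheet))
        stop("one track file per sample sheet row is required")
    vals <- vapply(files, readCoverage, numeric(length(bins)), bins = bins)
    dimnames(vals) <- NULL
    BinnedSignal(vals, bins, sampleSheet, stage = "raw")
}

#' Counts-per-million normalisation
#'
#' Scales every sample (column) so its bin values sum to one million. The
#' per-sample total is the sum over bin values, which is proportional to
#' the read total under uniform binning.
#'
#' @param x A [BinnedSignal] at stage `"raw"`.
#' @return A [BinnedSignal] at stage `"cpm"`.
#' @export
cpmNormalize <- function(x) {
    .requireStage(x, "raw", "cpmNormalize()")
    vals <- assay(x, "values")
    totals <- colSums(vals)
    if (any(totals <= 0))
        stop("sample(s) with all-zero counts: ",
             paste(colData(x)$sample_id[totals <= 0], collapse = ", "))
    out <- sweep(vals, 2L, totals, "/") * 1e6
    BinnedSignal(out, rowRanges(x), colData(x), stage = "cpm")
}

#' Subtract the matched IgG background track
#'
#' For every target sample, subtracts the CPM-scale IgG control track of the
#' same condition (or the single shared IgG track when only one is present).
#' Negative values are preserved. The result keeps only target columns.
#'
#' @param x A [BinnedSignal] at stage `"cpm"` containing target and
#'   `igg_control` columns.
#' @param control Optional explicit control: a numeric vector (one value per
#'   bin, used for every target sample) overriding the sample sheet
#'   matching.
#' @return A [BinnedSignal] at stage `"ctrl_subtracted"` with target
#'   columns only.
#' @export
subtractControl <- function(x, control = NULL) {
    .requireStage(x, "cpm", "subtractControl()")
    vals <- assay(x, "values")
    cd <- colData(x)
    isTarget <- cd$role == "target"
    if (!any(isTarget)) stop("no target samples in 'x'")
    if (is.null(control)) {
        iggIdx <- which(cd$role == "igg_control")
        if (length(iggIdx) == 0L)
            stop("no 'igg_control' sample present and no explicit 'control'")
        ctrlFor <- function(j) {
            same <- iggIdx[cd$condition[iggIdx] == cd$condition[j]]
            if (length(same) == 1L) return(vals[, same])
            if (length(same) == 0L && length(iggIdx) == 1L)
                return(vals[, iggIdx])
            stop("ambiguous IgG matching for sample ", cd$sample_id[j],
                 ": need exactly one IgG per condition or one shared")
        }
        out <- vapply(which(isTarget), function(j) vals[, j] - ctrlFor(j),
                      numeric(nrow(vals)))
    } else {
        if (length(control) != nrow(vals))
            stop("'control' must have one value per bin")
        out <- vals[, isTarget, drop = FALSE] - control
    }
    dimnames(out) <- NULL
    BinnedSignal(out, rowRanges(x), cd[isTarget, , drop = FALSE],
                 stage = "ctrl_subtracted")
}

#' Remove bins overlapping a denylist
#'
#' Bins overlapping any denylist interval by at least one base pair are
#' dropped from the matrix entirely. Usable at any stage (in the standard
#' pipeline it is applied before z-scoring so excluded bins never enter the
#' per-sample moments).
#'
#' @param x A [BinnedSignal].
#' @param denylist `GRanges` of regions to exclude.
#' @return A [BinnedSignal] at the same stage with offending bins removed.
#' @export
applyDenylist <- function(x, denylist) {
    if (length(denylist) == 0L) return(x)
    keep <- !overlapsAny(rowRanges(x), denylist)
    if (!any(keep))
        stop("denylist removes every bin")
    BinnedSignal(assay(x, "values")[keep, , drop = FALSE],
                 rowRanges(x)[keep], colData(x), stage = stage(x))
}

#' Per-sample z-scoring
#'
#' Converts every sample (column) to z scores over the retained bins — mean
#' zero, unit standard deviation (computed with one delta degree of
#' freedom) — to absorb small differences in dynamic range between
#' experiments.
#'
#' @param x A [BinnedSignal] at stage `"ctrl_subtracted"`.
#' @return A [BinnedSignal] at stage `"zscore"`.
#' @export
zscoreBins <- function(x) {
    .requireStage(x, "ctrl_subtracted", "zscoreBins()")
    vals <- assay(x, "values")
    mu <- colMeans(vals)
    sd <- sqrt(colSums(sweep(vals, 2L, mu)^2) / (nrow(vals) - 1L))
    if (any(sd == 0))
        stop("zero-variance sample(s): ",
             paste(colData(x)$sample_id[sd == 0], collapse = ", "))
    out <- sweep(sweep(vals, 2L, mu), 2L, sd, "/")
    BinnedSignal(out, rowRanges(x), colData(x), stage = "zscore")
}

#' Rolling-mean smoothing of z-scored bins
#'
#' Smooths every sample with the mean of rolling, centred windows of
#' `window` bins to produce final scores at bin resolution. An even window
#' cannot be symmetric: with `align = "center_left"` (default) the window
#' for bin *i* spans bins *i - 5 .. i + 4* at `window = 10`;
#' `"center_right"` uses *i - 4 .. i + 5*. Windows are clipped at
#' chromosome boundaries (and at gaps are NOT re-anchored: bins removed by
#' the denylist simply do not contribute, the mean being taken over the
#' available bins of the same chromosome within the index window).
#'
#' @param x A [BinnedSignal] at stage `"zscore"`.
#' @param window Window size in bins (>= 1).
#' @param align `"center_left"` or `"center_right"` window anchoring.
#' @return A [BinnedSignal] at stage `"smoothed"`.
#' @export
smoothBins <- function(x, window = 10L,
                       align = c("center_left", "center_right")) {
    .requireStage(x, "zscore", "smoothBins()")
    align <- match.arg(align)
    .assertScalar(window, "window", 1)
    window <- as.integer(window)
    left <- if (align == "center_left") window %/% 2L
            else window - 1L - window %/% 2L
    right <- window - 1L - left
    vals <- assay(x, "values")
    out <- vals
    chrom <- as.integer(seqnames(rowRanges(x)))
    for (c in unique(chrom)) {
        idx <- which(chrom == c)
        n <- length(idx)
        i <- seq_len(n)
        lo <- pmax(1L, i - left)
        hi <- pmin(n, i + right)
        for (j in seq_len(ncol(vals))) {
            cs <- cumsum(c(0, vals[idx, j]))
            out[idx, j] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
        }
    }
    BinnedSignal(out, rowRanges(x), colData(x), stage = "smoothed")
}
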