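#' Per-bin two-sample t test across replicates
#'
#' For every bin, compares the replicate values of the two conditions with a
#' two-sample t test on the final (smoothed) scores: equal-variance
#' Student's t by default, Welch's t optionally. Returns the mean
#' difference (first contrast level minus second, in smoothed-z units), the
#' t statistic, the two-sided p value, its Benjamini-Hochberg adjustment
#' over all bins, and the direction of change. Bins where the pooled
#' variance vanishes use a floor of 1e-12; when additionally the means are
#' equal, t = 0 and p = 1 by convention.
#'
#' @param x A [BinnedSignal] at stage `"smoothed"` (or `"zscore"`, for
#'   pipelines that test unsmoothed scores).
#' @param contrast Length-2 character: conditions to compare, difference
#'   taken as `contrast[1] - contrast[2]`.
#' @param varEqual Use the pooled-variance Student's t (default) or Welch's.
#' @return A `DataFrame` with columns `meanDiff`, `t`, `p`, `padj`,
#'   `direction`, one row per bin.
#' @export
perBinTest <- function(x, contrast = c("treated", "control"),
                       varEqual = TRUE) {
    .requireStage(x, c("smoothed", "zscore"), "perBinTest()")
    cd <- colData(x)
    a <- which(cd$condition == contrast[1] & cd$role == "target")
    b <- which(cd$condition == contrast[2] & cd$role == "target")
    if (length(a) < 2L || length(b) < 2L)
        stop("at least 2 replicates per condition are required (got ",
             length(a), " '", contrast[1], "' and ", length(b), " '",
             contrast[2], "')")
    va <- assay(x, "values")[, a, drop = FALSE]
    vb <- assay(x, "values")[, b, drop = FALSE]
    n1 <- ncol(va); n2 <- ncol(vb)
    m1 <- rowMeans(va); m2 <- rowMeans(vb)
    s1 <- .rowVars(va); s2 <- .rowVars(vb)
    d <- m1 - m2
    if (varEqual) {
        sp2 <- pmax(((n1 - 1L) * s1 + (n2 - 1L) * s2) / (n1 + n2 - 2L),
                    1e-12)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2L, length(d))
    } else {
        v1 <- pmax(s1, 1e-12) / n1
        v2 <- pmax(s2, 1e-12) / n2
        se <- sqrt(v1 + v2)
        df <- (v1 + v2)^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
    }
    t <- d / se
    t[d == 0] <- 0
    p <- 2 * stats::pt(-abs(t), df)
    DataFrame(meanDiff = d, t = t, p = p, padj = bhAdjust(p),
              direction = ifelse(d >= 0, "up", "down"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the adjusted value for the
#' i-th smallest p is `min over j >= i of p_(j) * m / j`, capped at 1.
#' A thin wrapper over [stats::p.adjust()] that additionally validates the
#' input range.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.002, 0.01, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Merge significant bins into differential domains
#'
#' Selects bins with BH-adjusted p below `alpha` whose sign matches the
#' requested direction and merges book-ended runs (gap 0 bp) into domains,
#' the equivalent of `bedtools merge -d 0` on significant bins. Bins
#' separated by any gap — an intervening non-significant bin, a denylist
#' hole, or a chromosome boundary — start a new domain.
#'
#' @param stats Per-bin statistics from [perBinTest()].
#' @param bins `GRanges` the statistics are aligned to.
#' @param alpha Adjusted-p threshold in (0, 1); the broad-mark analysis
#'   default is 0.005.
#' @param direction `"up"` (significantly higher in the first contrast
#'   level; default), `"down"`, or `"both"`.
#' @return A [DomainCallResult]; its `summary` is filled with the domain
#'   count, mean length and (bp, not workspace-relative) total length.
#' @export
callDomains <- function(stats, bins, alpha = 0.005,
                        direction = c("up", "down", "both")) {
    direction <- match.arg(direction)
    .assertScalar(alpha, "alpha", 0, 1, openLower = TRUE, openUpper = TRUE)
    if (nrow(stats) != length(bins))
        stop("'stats' and 'bins' must have matching length")
    wanted <- if (direction == "both") c("up", "down") else direction
    doms <- GRanges(seqinfo = seqinfo(bins))
    for (dir in wanted) {
        sig <- which(stats$padj < alpha & stats$direction == dir)
        if (length(sig) == 0L) next
        merged <- reduce(bins[sig], min.gapwidth = 1L)
        hit <- findOverlaps(bins[sig], merged)
        minPadj <- vapply(split(stats$padj[sig], S4Vectors::subjectHits(hit)),
                          min, numeric(1))
        mcols(merged)$direction <- dir
        mcols(merged)$score <- -log10(minPadj)
        doms <- c(doms, merged)
    }
    doms <- .sortGR(doms)
    if (length(doms)) names(doms) <- sprintf("domain_%04d", seq_along(doms))
    res <- new("DomainCallResult", binStats = stats, bins = bins,
               domains = doms, alpha = alpha, direction = direction,
               summary = list())
    res@summary <- list(
        n_domains = length(doms),
        mean_length_bp = if (length(doms)) mean(width(doms)) else NA_real_,
        total_length_bp = sum(width(doms)))
    res
}

#' Summarise called domains against a workspace
#'
#' Reports the domain count, mean domain length in bp, and the fraction of
#' the mappable workspace covered by domains.
#'
#' @param result A [DomainCallResult].
#' @param workspace `GRanges` of the mappable genome.
#' @return A list with `n_domains`, `mean_length_bp` (NA when no domains
#'   were called), `total_length_bp` and `genome_fraction`.
#' @export
summarizeDomains <- function(result, workspace) {
    doms <- domains(result)
    wsBp <- sum(as.numeric(width(workspace)))
    out <- list(n_domains = length(doms),
                mean_length_bp = if (length(doms)) mean(width(doms))
                                 else NA_real_,
                total_length_bp = sum(as.numeric(width(doms))),
                genome_fraction = sum(as.numeric(width(doms))) / wsBp)
    result@summary <- out
    out
}
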