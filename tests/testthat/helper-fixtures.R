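suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
    library(IRanges)
})

# tiny layout used across binning tests
tinyLayout <- function(lengths = c(chr1 = 10000), binSize = 1000) {
    GenomeLayout(lengths, binSize = binSize)
}

# bins-by-samples signal at an arbitrary stage, 3v3 target design
signalFromMatrix <- function(values, layout = NULL, stage = "smoothed",
                             conditions = NULL) {
    n <- nrow(values)
    if (is.null(layout))
        layout <- tinyLayout(c(chr1 = n * 1000))
    bins <- makeBins(layout)[seq_len(n)]
    k <- ncol(values)
    if (is.null(conditions))
        conditions <- rep(c("control", "treated"), each = k / 2)
    sheet <- data.frame(sample_id = paste0("s", seq_len(k)),
                        condition = conditions,
                        replicate = ave(seq_len(k), conditions,
                                        FUN = seq_along),
                        role = "target")
    BinnedSignal(values, bins, sheet, stage = stage)
}

# write a bedGraph from 0-based record triples
writeBedGraphFile <- function(chrom, start0, end0, value, file) {
    writeLines(paste(chrom, start0, end0, value, sep = "\t"), file)
    file
}

# independent rolling-mean oracle: naive per-position loop
rollMeanOracle <- function(x, left, right) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
        mean(x[max(1, i - left):min(n, i + right)])
    }, numeric(1))
}

# independent step-up FDR oracle, straight from the definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        r <- which(o == i)  # rank of p[i]
        adj[i] <- min(1, min(p[o][r:m] * m / (r:m)))
    }
    adj
}

# expression experiment with explicit per-condition gene means
expressionFromMeans <- function(means, conditions, reps = 4, dispersion = 0.05,
                                seed = 1) {
    set.seed(seed)
    genes <- rownames(means)
    cols <- expand.grid(replicate = seq_len(reps), condition = conditions,
                        stringsAsFactors = FALSE)[, 2:1]
    counts <- sapply(seq_len(nrow(cols)), function(j)
        rnbinom(length(genes), mu = means[, cols$condition[j]],
                size = 1 / dispersion))
    dimnames(counts) <- list(genes,
                             paste0(cols$condition, "_r", cols$replicate))
    SummarizedExperiment(assays = list(counts = counts),
                         colData = DataFrame(cols,
                             row.names = colnames(counts)))
}

# exhaustive enumeration of the expected overlap of one segment with an
# annotation: average over every legal start position in the workspace
enumeratedExpectedOverlap <- function(segLen, wsIntervals, annIntervals) {
    # intervals given as 0-based [start, end) pairs on one chromosome
    annBases <- unlist(lapply(annIntervals, function(iv)
        seq(iv[1], iv[2] - 1)))
    ovs <- unlist(lapply(wsIntervals, function(iv) {
        starts <- iv[1]:(iv[2] - segLen)
        vapply(starts, function(s)
            sum(annBases >= s & annBases < s + segLen), numeric(1))
    }))
    mean(ovs)
}

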