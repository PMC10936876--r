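#' Simulate replicate coverage tracks with planted differential domains
#'
#' Draws per-bin counts for replicate target tracks in two conditions
#' (control and treated) plus one IgG background track per condition.
#' Counts are i.i.d. per replicate with mean `baselineRate` everywhere,
#' except that treated replicates have mean `baselineRate * effect` inside
#' each planted domain. IgG tracks have mean `iggRate` everywhere. Coverage
#' is emitted at exact bin resolution — the analysis begins at binned
#' counts, so read-level simulation would add cost without exercising more
#' of the computation.
#'
#' @param layout A [GenomeLayout].
#' @param truth A [SimulationTruth] (use `NULL` or a truth with no planted
#'   domains for a null simulation).
#' @param baselineRate Mean per-bin count of target tracks (> 0).
#' @param noiseModel `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); ignored for Poisson noise.
#' @param repsPerCondition Target replicates per condition (>= 2 for the
#'   downstream test stages).
#' @param iggRate Mean per-bin count of the IgG tracks.
#' @param iggPerCondition Simulate one IgG track per condition instead of
#'   a single shared one. The default is a shared track: subtracting a
#'   condition-specific background track injects per-bin noise that is
#'   common to all replicates of a condition, which a replicate-level t
#'   test mistakes for signal (see the package vignette).
#' @param seed Integer seed; output is deterministic given it.
#' @param outdir Optional directory; when given, one bedGraph per sample is
#'   written there (named `<sample_id>.bedGraph`) along with
#'   `samples.tsv`.
#' @return A [BinnedSignal] at stage `"raw"` whose columns are all target
#'   replicates followed by the IgG tracks, with the sample sheet in
#'   `colData()`.
#' @examples
#' g <- simulateGenome(1e5, nChrom = 1, nGenes = 5, seed = 1)
#' tr <- plantTruth(g$layout, g$annotation, g$genes, nDomains = 2, seed = 1)
#' bs <- simulateCoverage(g$layout, tr, seed = 1)
#' bs
#' @export
simulateCoverage <- function(layout, truth, baselineRate = 25,
                             noiseModel = c("poisson", "negative_binomial"),
                             dispersion = 0.05, repsPerCondition = 3L,
                             iggRate = 2, iggPerCondition = FALSE,
                             seed = 1L, outdir = NULL) {
    noiseModel <- match.arg(noiseModel)
    .assertScalar(baselineRate, "baselineRate", 0, openLower = TRUE)
    .assertScalar(iggRate, "iggRate", 0, openLower = TRUE)
    if (repsPerCondition < 1L) stop("'repsPerCondition' must be >= 1")
    if (noiseModel == "negative_binomial")
        .assertScalar(dispersion, "dispersion", 0, openLower = TRUE)
    set.seed(stageSeed(seed, "coverage"))

    bins <- makeBins(layout)
    nb <- length(bins)
    mu0 <- rep(baselineRate, nb)
    muTreated <- mu0
    if (!is.null(truth) && length(plantedDomains(truth))) {
        hit <- findOverlaps(bins, plantedDomains(truth))
        eff <- mcols(plantedDomains(truth))$effect[S4Vectors::subjectHits(hit)]
        muTreated[S4Vectors::queryHits(hit)] <- baselineRate * eff
    }

    draw <- function(mu) {
        if (noiseModel == "poisson") stats::rpois(nb, mu)
        else stats::rnbinom(nb, mu = mu, size = 1 / dispersion)
    }
    conditions <- c("control", "treated")
    iggCond <- if (iggPerCondition) conditions else "shared"
    sheet <- data.frame(
        sample_id = c(paste0(rep(conditions, each = repsPerCondition),
                             "_rep", seq_len(repsPerCondition)),
                      paste0("igg_", iggCond)),
        condition = c(rep(conditions, each = repsPerCondition), iggCond),
        replicate = c(rep(seq_len(repsPerCondition), 2L),
                      rep(1L, length(iggCond))),
        role = c(rep("target", 2L * repsPerCondition),
                 rep("igg_control", length(iggCond))))
    vals <- matrix(0, nrow = nb, ncol = nrow(sheet))
    for (j in seq_len(nrow(sheet))) {
        mu <- if (sheet$role[j] == "igg_control") rep(iggRate, nb)
              else if (sheet$condition[j] == "treated") muTreated else mu0
        vals[, j] <- draw(mu)
    }
    bs <- BinnedSignal(vals, bins, sheet, stage = "raw")
    if (!is.null(outdir)) writeCoverageTracks(bs, outdir)
    bs
}

#' Write one bedGraph per sample of a raw binned-signal object
#'
#' @param x A [BinnedSignal] (any stage; values are written as-is).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the paths written (tracks plus `samples.tsv`).
#' @export
writeCoverageTracks <- function(x, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    bins <- rowRanges(x)
    vals <- assay(x, "values")
    paths <- character(0)
    for (j in seq_len(ncol(x))) {
        f <- file.path(outdir, paste0(colData(x)$sample_id[j], ".bedGraph"))
        writeBedGraph(bins, vals[, j], f)
        paths <- c(paths, f)
    }
    sheetFile <- file.path(outdir, "samples.tsv")
    utils::write.table(as.data.frame(colData(x)), sheetFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(c(paths, sheetFile))
}

#' Simulate three-condition expression counts with planted responsive genes
#'
#' Draws negative-binomial gene-level counts for the conditions `control`,
#' `treated_60` and `treated_60_KD` (optionally also `treated_30`).
#' Responsive genes have mean `baselineMean * inducedFold` in the treated
#' condition; knockdown-dependent responsive genes revert to the baseline
#' mean under knockdown, while knockdown-independent responsive genes keep
#' the induced mean. All other genes stay at baseline throughout.
#'
#' @param genes Gene table from [simulateGenome()].
#' @param truth A [SimulationTruth] carrying the responsive / dependent sets.
#' @param repsPerCondition Replicates per condition.
#' @param baselineMean Baseline negative-binomial mean count.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param inducedFold Fold induction of responsive genes in the treated
#'   condition (> 1 to plant a signal; 1 gives an exchangeable null).
#' @param conditions Conditions to simulate.
#' @param seed Integer seed.
#' @param file Optional path; when given the counts are written as TSV
#'   (gene_id column plus one column per sample).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and `colData` columns `condition` and `replicate`.
#' @examples
#' g <- simulateGenome(2e5, nChrom = 1, nGenes = 20, seed = 1)
#' tr <- plantTruth(g$layout, g$annotation, g$genes, nDomains = 2, seed = 1)
#' se <- simulateExpression(g$genes, tr, seed = 1)
#' table(colData(se)$condition)
#' @export
simulateExpression <- function(genes, truth, repsPerCondition = 4L,
                               baselineMean = 200, dispersion = 0.05,
                               inducedFold = 4,
                               conditions = c("control", "treated_60",
                                              "treated_60_KD"),
                               seed = 1L, file = NULL) {
    .assertScalar(dispersion, "dispersion", 0, openLower = TRUE)
    .assertScalar(inducedFold, "inducedFold", 1)
    set.seed(stageSeed(seed, "expression"))
    ids <- genes$gene_id
    responsive <- ids %in% responsiveGenes(truth)
    dependent <- ids %in% dependentGenes(truth)

    muFor <- function(cond) {
        mu <- rep(baselineMean, length(ids))
        if (cond %in% c("treated_30", "treated_60"))
            mu[responsive] <- baselineMean * inducedFold
        if (cond == "treated_60_KD")
            mu[responsive & !dependent] <- baselineMean * inducedFold
        mu
    }
    cols <- expand.grid(replicate = seq_len(repsPerCondition),
                        condition = conditions,
                        stringsAsFactors = FALSE)[, 2:1]
    counts <- matrix(0L, nrow = length(ids), ncol = nrow(cols),
                     dimnames = list(ids, paste0(cols$condition, "_rep",
                                                 cols$replicate)))
    for (j in seq_len(nrow(cols)))
        counts[, j] <- stats::rnbinom(length(ids), mu = muFor(cols$condition[j]),
                                      size = 1 / dispersion)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = DataFrame(cols,
                                   row.names = colnames(counts)))
    if (!is.null(file)) {
        df <- data.frame(gene_id = ids, counts, check.names = FALSE)
        utils::write.table(df, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    se
}
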