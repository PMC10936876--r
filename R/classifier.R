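.counts <- function(se) {
    m <- assay(se, "counts")
    if (any(m < 0)) stop("counts must be non-negative")
    m
}

#' Counts-per-million matrix of an expression experiment
#'
#' @param se `SummarizedExperiment` with a `"counts"` assay.
#' @return Numeric matrix of CPM values.
#' @export
cpmMatrix <- function(se) {
    m <- .counts(se)
    totals <- colSums(m)
    if (any(totals <= 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(m)[totals <= 0], collapse = ", "))
    sweep(m, 2L, totals, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Retains genes with a counts-per-million value greater than
#' `cpmThreshold` in at least `minSamples` samples.
#'
#' @param se `SummarizedExperiment` with a `"counts"` assay.
#' @param cpmThreshold CPM cutoff (default 10).
#' @param minSamples Minimum number of samples above the cutoff (default 2).
#' @return The filtered `SummarizedExperiment`.
#' @export
filterGenes <- function(se, cpmThreshold = 10, minSamples = 2L) {
    keep <- rowSums(cpmMatrix(se) > cpmThreshold) >= minSamples
    if (!any(keep)) stop("all genes removed by the expression filter")
    se[keep, ]
}

#' Differential expression between two conditions
#'
#' The default test is Welch's t on log2(CPM + pseudocount), gene by gene;
#' the log fold change is the difference of group means on that scale
#' (`contrast[1] - contrast[2]`). P values are adjusted across all tested
#' genes (Benjamini-Hochberg by default, Bonferroni optionally). The
#' classification stages also accept externally computed tables (columns
#' `gene_id`, `lfc`, `padj`), so a negative-binomial test such as edgeR's
#' exact test can be plugged in unchanged.
#'
#' @param se `SummarizedExperiment` with assay `"counts"` and a `condition`
#'   column in `colData()`.
#' @param contrast Length-2 character vector of condition levels.
#' @param pseudocount Added to CPM before log2 (default 1).
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return `data.frame` with `gene_id`, `lfc`, `t`, `p`, `padj`, `meanA`,
#'   `meanB` (group means in log2(CPM + pseudocount) units).
#' @export
deTest <- function(se, contrast, pseudocount = 1, adjust = c("BH",
                   "bonferroni")) {
    adjust <- match.arg(adjust)
    cond <- colData(se)$condition
    a <- which(cond == contrast[1])
    b <- which(cond == contrast[2])
    if (length(a) < 2L || length(b) < 2L)
        stop("at least 2 replicates per condition are required for ",
             paste(contrast, collapse = " vs "))
    lg <- log2(cpmMatrix(se) + pseudocount)
    va <- lg[, a, drop = FALSE]; vb <- lg[, b, drop = FALSE]
    n1 <- ncol(va); n2 <- ncol(vb)
    m1 <- rowMeans(va); m2 <- rowMeans(vb)
    v1 <- pmax(.rowVars(va), 1e-12) / n1
    v2 <- pmax(.rowVars(vb), 1e-12) / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    t[m1 == m2] <- 0
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(gene_id = rownames(se), lfc = m1 - m2, t = t, p = p,
               padj = if (adjust == "BH") bhAdjust(p)
                      else pmin(p * length(p), 1),
               meanA = m1, meanB = m2, row.names = NULL)
}

#' Call up-regulated genes
#'
#' Genes with log fold change above `lfcMin` and adjusted p below `alpha`.
#'
#' @param de A differential table with columns `gene_id`, `lfc`, `padj`
#'   (from [deTest()] or an external test).
#' @param lfcMin Log fold change threshold (default 0.5, exclusive).
#' @param alpha Adjusted-p threshold (default 0.05, exclusive).
#' @return Character vector of gene identifiers.
#' @export
callUp <- function(de, lfcMin = 0.5, alpha = 0.05) {
    de$gene_id[de$lfc > lfcMin & de$padj < alpha]
}

# per-condition means of log2(CPM + 1), row-scaled to z across conditions
.scaledProfiles <- function(se, genes, conditions, pseudocount = 1) {
    lg <- log2(cpmMatrix(se) + pseudocount)[genes, , drop = FALSE]
    cond <- colData(se)$condition
    prof <- vapply(conditions,
                   function(cc) rowMeans(lg[, cond == cc, drop = FALSE]),
                   numeric(length(genes)))
    if (is.null(dim(prof)))
        prof <- matrix(prof, nrow = 1L,
                       dimnames = list(genes, conditions))
    mu <- rowMeans(prof)
    sd <- sqrt(.rowVars(prof))
    flat <- sd == 0
    if (any(flat)) {
        warning(sum(flat), " gene(s) with identical profiles across ",
                "conditions; their scaled profile is set to 0")
        sd[flat] <- 1
    }
    (prof - mu) / sd
}

#' Cluster up-regulated genes across conditions
#'
#' Hierarchically clusters the up-regulated genes on their row-scaled
#' per-condition mean expression profiles (z across the per-condition
#' means of log2(CPM+1)), Euclidean distance, complete linkage, tree cut
#' into `k` clusters.
#'
#' @param se `SummarizedExperiment` with assay `"counts"`.
#' @param up Character vector of gene identifiers to cluster.
#' @param conditions Conditions defining the profile (default the three
#'   used for dependence classification).
#' @param k Number of clusters (default 2).
#' @return Named integer vector of cluster assignments.
#' @export
clusterUpGenes <- function(se, up,
                           conditions = c("control", "treated_60",
                                          "treated_60_KD"), k = 2L) {
    if (length(up) == 0L) stop("'up' is empty")
    if (length(up) < k) stop("fewer genes than clusters requested")
    missingCond <- setdiff(conditions, unique(colData(se)$condition))
    if (length(missingCond))
        stop("condition(s) absent from the experiment: ",
             paste(missingCond, collapse = ", "))
    prof <- .scaledProfiles(se, up, conditions)
    cl <- stats::cutree(stats::hclust(stats::dist(prof), method = "complete"),
                        k = k)
    names(cl) <- up
    cl
}

#' Split up-regulated genes into knockdown-dependent and -independent sets
#'
#' Reproduces the three-condition dependence logic: among the clusters of
#' up-regulated genes, the candidate cluster is the one with the largest
#' mean difference between the treated and treated-plus-knockdown scaled
#' profiles; within it, genes that are significantly differentially
#' expressed between those two conditions (adjusted p < `alpha`) and lower
#' under knockdown are called dependent. All remaining up-regulated genes
#' are independent, so the two sets always partition the up-regulated set.
#'
#' @param se `SummarizedExperiment` with assay `"counts"`.
#' @param up Character vector of stimulation-up-regulated genes.
#' @param clusters Cluster assignment from [clusterUpGenes()].
#' @param alpha Adjusted-p threshold for the knockdown contrast.
#' @param kdContrast Length-2 character: treated and knockdown condition
#'   labels.
#' @return A list with `up`, `dependent`, `independent`,
#'   `candidate_cluster` and the knockdown differential table `de_kd`.
#' @export
classifyDependence <- function(se, up, clusters, alpha = 0.05,
                               kdContrast = c("treated_60",
                                              "treated_60_KD")) {
    if (!all(kdContrast %in% colData(se)$condition))
        stop("knockdown classification requires conditions: ",
             paste(kdContrast, collapse = ", "))
    profConds <- intersect(unique(c("control", kdContrast)),
                           unique(colData(se)$condition))
    prof3 <- .scaledProfiles(se, up, profConds)
    dKD <- prof3[, kdContrast[1]] - prof3[, kdContrast[2]]
    score <- tapply(dKD, clusters[up], mean)
    candidate <- as.integer(names(score)[which.max(score)])
    inCand <- up[clusters[up] == candidate]

    deKD <- deTest(se[rownames(se) %in% up, ], kdContrast)
    rownames(deKD) <- deKD$gene_id
    sig <- deKD[inCand, , drop = FALSE]
    dependent <- sig$gene_id[sig$padj < alpha & sig$lfc > 0]
    list(up = up, dependent = sort(dependent),
         independent = sort(setdiff(up, dependent)),
         candidate_cluster = candidate, de_kd = deKD)
}

#' Full three-condition response classification
#'
#' Runs the complete gene-set logic: expression filter, differential test
#' of treated versus control, up-regulated call (lfc > `lfcMin`, adjusted
#' p < `alpha`), hierarchical clustering across the three conditions, and
#' the knockdown-dependence split.
#'
#' @param se `SummarizedExperiment` with assay `"counts"` and `condition`
#'   in `colData()` covering control, treated and treated-plus-knockdown.
#' @param treated,control,knockdown Condition labels.
#' @param cpmThreshold,minSamples Expression-filter parameters.
#' @param lfcMin,alpha Up-regulation thresholds.
#' @param k Number of clusters.
#' @param de Optional external differential table (columns `gene_id`,
#'   `lfc`, `padj`) for the treated-vs-control contrast, replacing the
#'   built-in test.
#' @return A list with `up`, `dependent`, `independent`, `clusters`,
#'   `candidate_cluster`, `de` (treated vs control) and `de_kd`.
#' @export
classifyResponse <- function(se, treated = "treated_60",
                             control = "control",
                             knockdown = "treated_60_KD",
                             cpmThreshold = 10, minSamples = 2L,
                             lfcMin = 0.5, alpha = 0.05, k = 2L,
                             de = NULL) {
    fse <- filterGenes(se, cpmThreshold, minSamples)
    if (is.null(de)) de <- deTest(fse, c(treated, control))
    up <- callUp(de, lfcMin = lfcMin, alpha = alpha)
    up <- intersect(up, rownames(fse))
    if (length(up) == 0L)
        return(list(up = character(0), dependent = character(0),
                    independent = character(0), clusters = integer(0),
                    candidate_cluster = NA_integer_, de = de,
                    de_kd = NULL))
    if (length(up) < k) k <- length(up)
    clusters <- clusterUpGenes(fse, up,
                               conditions = c(control, treated, knockdown),
                               k = max(k, 1L))
    dep <- classifyDependence(fse, up, clusters, alpha = alpha,
                              kdContrast = c(treated, knockdown))
    c(list(clusters = clusters, de = de), dep)
}
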