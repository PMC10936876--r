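# Fixtures include a pool of unchanging background genes so library depth is
# stable across conditions: CPM is compositional, and a design in which every
# gene responds would cancel its own signal in CPM space.
backgroundMeans <- function(n, mean = 200) {
    m <- matrix(mean, n, 3,
                dimnames = list(sprintf("bg%03d", seq_len(n)),
                                c("control", "treated_60",
                                  "treated_60_KD")))
    m
}

test_that("the expression filter keeps genes by CPM in enough samples", {
    # 3 samples, equal depth 1e5 => CPM ~ count * 10
    counts <- rbind(kept = c(120, 110, 0),
                    dropped = c(120, 0, 0),
                    low = c(5, 5, 5),
                    filler = c(99755, 99885, 99995))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(condition = c("control", "treated_60",
                                          "treated_60_KD"),
                            replicate = c(1, 1, 1)))
    out <- filterGenes(se, cpmThreshold = 1000, minSamples = 2)
    expect_true("kept" %in% rownames(out))
    expect_false("dropped" %in% rownames(out))
    expect_false("low" %in% rownames(out))
    expect_equal(nrow(filterGenes(se, cpmThreshold = 0, minSamples = 2)),
                 3L)
    expect_error(filterGenes(se, cpmThreshold = 1e9), "all genes")
})

test_that("identical groups give zero fold change and unit p", {
    means <- backgroundMeans(6)[, 1:2]
    se <- expressionFromMeans(means, c("control", "treated_60"), seed = 2)
    cm <- assay(se, "counts")
    dup <- cbind(cm[, 1:4], cm[, 1:4])
    colnames(dup) <- paste0("s", 1:8)
    se2 <- SummarizedExperiment(
        assays = list(counts = dup),
        colData = DataFrame(condition = rep(c("control", "treated_60"),
                                            each = 4),
                            replicate = rep(1:4, 2),
                            row.names = colnames(dup)))
    de <- deTest(se2, c("treated_60", "control"))
    expect_true(all(de$lfc == 0))
    expect_true(all(de$p == 1))
})

test_that("the log fold change matches the hand-computed ratio", {
    # equal-depth design so CPM is exact: one gene at CPM 100 vs 400,
    # remainder as filler
    g <- rbind(gene = c(rep(100, 3), rep(400, 3)),
               filler = 1e6 - c(rep(100, 3), rep(400, 3)))
    se <- SummarizedExperiment(
        assays = list(counts = g),
        colData = DataFrame(condition = rep(c("control", "treated_60"),
                                            each = 3),
                            replicate = rep(1:3, 2),
                            row.names = paste0("s", 1:6)))
    de <- deTest(se, c("treated_60", "control"))
    expect_equal(de$lfc[de$gene_id == "gene"],
                 log2(401) - log2(101), tolerance = 1e-12)
})

test_that("the default test is calibrated under the null", {
    means <- backgroundMeans(400)[, 1:2]
    se <- expressionFromMeans(means, c("control", "treated_60"),
                              reps = 4, seed = 10)
    de <- deTest(se, c("treated_60", "control"))
    frac <- mean(de$p < 0.05)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)
    expect_equal(length(callUp(de)), 0L)
})

test_that("up-regulation thresholds are applied as joint conditions", {
    de <- data.frame(gene_id = c("a", "b", "c", "d"),
                     lfc = c(0.6, 0.4, 0.6, 2.0),
                     padj = c(0.01, 0.001, 0.06, 0.04))
    expect_equal(callUp(de), c("a", "d"))
    expect_equal(callUp(de, lfcMin = 0.3), c("a", "b", "d"))
    expect_equal(callUp(de, alpha = 0.005), character(0))
})

test_that("clustering separates reverting from persisting profiles", {
    genes <- sprintf("g%02d", 1:30)
    responsive <- cbind(control = rep(100, 30),
                        treated_60 = rep(400, 30),
                        treated_60_KD = c(rep(100, 10), rep(400, 20)))
    rownames(responsive) <- genes
    means <- rbind(responsive, backgroundMeans(120))
    se <- expressionFromMeans(means,
                              c("control", "treated_60", "treated_60_KD"),
                              reps = 4, dispersion = 0.02, seed = 4)
    cl <- clusterUpGenes(se, genes, k = 2)
    # modal cluster of each planted class differs, with few strays
    modal <- function(x) as.integer(names(which.max(table(x))))
    m1 <- modal(cl[1:10]); m2 <- modal(cl[11:30])
    expect_false(m1 == m2)
    expect_gte(mean(cl[1:10] == m1), 0.9)
    expect_gte(mean(cl[11:30] == m2), 0.9)
    # k = number of genes gives singletons
    clN <- clusterUpGenes(se, genes, k = 30)
    expect_equal(length(unique(clN)), 30L)
    # degenerate identical profiles are flagged
    seF <- SummarizedExperiment(
        assays = list(counts = matrix(200L, 5, 9,
            dimnames = list(paste0("f", 1:5), paste0("s", 1:9)))),
        colData = DataFrame(condition = rep(c("control", "treated_60",
                                              "treated_60_KD"), each = 3),
                            replicate = rep(1:3, 3),
                            row.names = paste0("s", 1:9)))
    expect_warning(clusterUpGenes(seF, paste0("f", 1:5), k = 2),
                   "identical profiles")
})

test_that("dependence classification recovers planted gene classes", {
    genes <- sprintf("g%03d", 1:100)
    dep <- genes[1:20]
    responsive <- cbind(control = rep(50, 100),
                        treated_60 = rep(200, 100),
                        treated_60_KD = c(rep(50, 20), rep(200, 80)))
    rownames(responsive) <- genes
    means <- rbind(responsive, backgroundMeans(400, 120))
    se <- expressionFromMeans(means,
                              c("control", "treated_60", "treated_60_KD"),
                              reps = 4, dispersion = 0.05, seed = 5)
    res <- classifyResponse(se)
    expect_setequal(union(res$dependent, res$independent), res$up)
    expect_length(intersect(res$dependent, res$independent), 0L)
    # planted responsive genes dominate the up call
    expect_gte(length(intersect(res$up, genes)) / length(genes), 0.9)
    sens <- length(intersect(res$dependent, dep)) / length(dep)
    spec <- length(intersect(res$independent, setdiff(genes, dep))) /
        length(setdiff(genes, dep))
    expect_gte(sens, 0.9)
    expect_gte(spec, 0.9)
})

test_that("a missing knockdown condition is a classification error", {
    genes <- paste0("g", 1:10)
    responsive <- cbind(control = rep(100, 10), treated_60 = rep(400, 10))
    rownames(responsive) <- genes
    means <- rbind(responsive, backgroundMeans(40)[, 1:2])
    se <- expressionFromMeans(means, c("control", "treated_60"), seed = 6)
    expect_error(classifyResponse(se), "treated_60_KD")
})

test_that("null dependence yields an (almost) empty dependent set", {
    genes <- sprintf("g%03d", 1:80)
    responsive <- cbind(control = rep(50, 80), treated_60 = rep(200, 80),
                        treated_60_KD = rep(200, 80))
    rownames(responsive) <- genes
    means <- rbind(responsive, backgroundMeans(320, 120))
    se <- expressionFromMeans(means,
                              c("control", "treated_60", "treated_60_KD"),
                              reps = 4, seed = 7)
    res <- classifyResponse(se)
    expect_gte(length(res$up), 60L)
    expect_lte(length(res$dependent), ceiling(0.05 * length(res$up)) + 1)
    expect_setequal(union(res$dependent, res$independent), res$up)
})
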