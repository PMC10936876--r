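test_that("makeBins tiles chromosomes with a truncated terminal bin", {
    b <- makeBins(tinyLayout(c(chr1 = 2500)))
    expect_equal(start(b) - 1L, c(0L, 1000L, 2000L))
    expect_equal(end(b), c(1000L, 2000L, 2500L))

    b1 <- makeBins(tinyLayout(c(chr1 = 1000)))
    expect_equal(length(b1), 1L)
    expect_equal(width(b1), 1000L)

    b2 <- makeBins(tinyLayout(c(chr1 = 1500, chr2 = 500)))
    expect_equal(as.character(seqnames(b2)), c("chr1", "chr1", "chr2"))
    expect_equal(width(b2), c(1000L, 500L, 500L))
})

test_that("readCoverage averages record values over bin bases", {
    bins <- makeBins(tinyLayout(c(chr1 = 1000)))
    f <- withr::local_tempfile(fileext = ".bedGraph")

    writeBedGraphFile("chr1", 0, 1000, 4, f)
    expect_equal(readCoverage(f, bins), 4)

    writeBedGraphFile("chr1", 0, 500, 4, f)
    expect_equal(readCoverage(f, bins), 2)  # 500 bases of 4, 500 of 0

    writeLines(c("chr1\t0\t600\t1", "chr1\t600\t1000\t6"), f)
    expect_equal(readCoverage(f, bins), (600 * 1 + 400 * 6) / 1000)
})

test_that("readCoverage skips unknown chromosomes with a warning", {
    bins <- makeBins(tinyLayout(c(chr1 = 1000)))
    f <- withr::local_tempfile(fileext = ".bedGraph")
    writeLines(c("chr1\t0\t1000\t2", "chrUn\t0\t100\t9"), f)
    expect_warning(v <- readCoverage(f, bins), "unknown chromosome")
    expect_equal(v, 2)
})

test_that("binned means conserve total signal mass", {
    layout <- tinyLayout(c(chr1 = 10000))
    bins <- makeBins(layout)
    set.seed(42)
    # random non-overlapping records from a partition of the chromosome
    cuts <- sort(sample(1:9999, 30))
    s0 <- c(0, cuts); e0 <- c(cuts, 10000)
    val <- round(runif(length(s0), 0, 10), 2)
    f <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraphFile("chr1", s0, e0, val, f)
    v <- readCoverage(f, bins)
    expect_equal(sum(v * width(bins)), sum(val * (e0 - s0)),
                 tolerance = 1e-9)
})

test_that("CPM normalisation scales every sample to one million", {
    m <- signalFromMatrix(cbind(c(10, 90), c(25, 25)), stage = "raw",
                          conditions = c("control", "treated"))
    out <- cpmNormalize(m)
    expect_equal(stage(out), "cpm")
    expect_equal(assay(out)[, 1], c(1e5, 9e5))
    expect_equal(unname(colSums(assay(out))), c(1e6, 1e6))
    # all-equal bins land at 1e6 / n_bins each
    flat <- cpmNormalize(signalFromMatrix(matrix(7, 4, 2), stage = "raw"))
    expect_true(all(assay(flat) == 1e6 / 4))
    # all-zero samples are an error
    z <- signalFromMatrix(cbind(c(0, 0), c(1, 1)), stage = "raw")
    expect_error(cpmNormalize(z), "all-zero")
})

test_that("control subtraction matches targets to their IgG track", {
    vals <- cbind(c(5, 3), c(6, 2), c(1, 4))
    bins <- makeBins(tinyLayout(c(chr1 = 2000)))
    sheet <- data.frame(sample_id = c("t1", "t2", "igg"),
                        condition = c("treated", "treated", "shared"),
                        replicate = c(1, 2, 1),
                        role = c("target", "target", "igg_control"))
    x <- BinnedSignal(vals, bins, sheet, stage = "cpm")
    out <- subtractControl(x)
    expect_equal(stage(out), "ctrl_subtracted")
    expect_equal(ncol(out), 2L)
    expect_equal(assay(out)[, 1], c(4, -1))   # negatives preserved
    expect_equal(assay(out)[, 2], c(5, -2))
    # target == control gives all zeros
    x2 <- BinnedSignal(cbind(c(1, 4), c(1, 4), c(1, 4)), bins, sheet,
                       stage = "cpm")
    expect_true(all(assay(subtractControl(x2)) == 0))
    # explicit zero control is the identity on targets
    out0 <- subtractControl(x, control = c(0, 0))
    expect_equal(unname(assay(out0)), vals[, 1:2])
})

test_that("denylist filtering drops any bin overlapping by >= 1 bp", {
    m <- signalFromMatrix(matrix(1, 5, 2), stage = "raw")
    deny <- GRanges("chr1", IRanges(1501, 1600))
    out <- applyDenylist(m, deny)
    expect_equal(nrow(out), 4L)
    expect_false(any(overlapsAny(rowRanges(out), deny)))
    # empty denylist is the identity
    expect_identical(assay(applyDenylist(m, GRanges())), assay(m))
    # removing everything is an error
    expect_error(applyDenylist(m, GRanges("chr1", IRanges(1, 5000))),
                 "every bin")
})

test_that("z-scoring yields exact column moments and flags degeneracy", {
    m <- signalFromMatrix(cbind(c(1, 2, 3), c(4, 8, 6)),
                          stage = "ctrl_subtracted")
    out <- zscoreBins(m)
    expect_equal(stage(out), "zscore")
    expect_equal(assay(out)[, 1], c(-1, 0, 1))
    expect_equal(unname(colMeans(assay(out))), c(0, 0))
    expect_equal(unname(apply(assay(out), 2, sd)), c(1, 1))
    flat <- signalFromMatrix(cbind(c(5, 5, 5), c(1, 2, 3)),
                             stage = "ctrl_subtracted")
    expect_error(zscoreBins(flat), "s1")
})

test_that("smoothing equals the naive rolling-mean oracle", {
    set.seed(9)
    n <- 57
    x <- matrix(rnorm(2 * n), n, 2)
    m <- signalFromMatrix(x, stage = "zscore")
    out <- assay(smoothBins(m, window = 10))
    for (j in 1:2)
        expect_equal(out[, j], rollMeanOracle(x[, j], 5, 4))
    # right-anchored alternative window
    outR <- assay(smoothBins(m, window = 10, align = "center_right"))
    expect_equal(outR[, 1], rollMeanOracle(x[, 1], 4, 5))
    # an impulse spreads over exactly one window
    imp <- matrix(0, 21, 2); imp[11, ] <- 10
    sm <- assay(smoothBins(signalFromMatrix(imp, stage = "zscore"),
                           window = 10))
    expect_equal(sm[, 1], rollMeanOracle(imp[, 1], 5, 4))
    expect_equal(sum(sm[, 1] > 0), 10)
})

test_that("smoothing respects chromosome boundaries", {
    layout <- tinyLayout(c(chr1 = 5000, chr2 = 1000))
    vals <- matrix(c(rep(1, 5), 100, rep(1, 5), 100), ncol = 2)
    m <- signalFromMatrix(vals, layout = layout, stage = "zscore")
    out <- unname(assay(smoothBins(m, window = 10)))
    # single-bin chromosome is untouched regardless of window
    expect_equal(out[6, 1], 100)
    # chr1 bins never see the chr2 value
    expect_true(all(out[1:5, 1] == 1))
    # constant column stays constant within a chromosome
    expect_equal(out[1:5, 2], rep(1, 5))
})

test_that("the pipeline stage order is enforced", {
    raw <- signalFromMatrix(matrix(1:6, 3, 2), stage = "raw")
    expect_error(zscoreBins(raw), "stage")
    expect_error(smoothBins(raw), "stage")
    expect_error(subtractControl(raw), "stage")
    z <- signalFromMatrix(matrix(rnorm(6), 3, 2), stage = "zscore")
    expect_error(cpmNormalize(z), "stage")
    expect_error(zscoreBins(z), "stage")
})
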