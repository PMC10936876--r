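test_that("per-bin t statistics match the pooled-variance formula", {
    a <- c(2.1, 1.9, 2.0); b <- c(0.0, 0.1, -0.1)
    m <- signalFromMatrix(rbind(c(b, a), c(1, 2, 3, 1, 2, 3)))
    st <- perBinTest(m, contrast = c("treated", "control"))
    # closed form: t = (mA - mB) / sqrt(sp2 * (1/3 + 1/3))
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    tExp <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
    expect_equal(st$t[1], tExp, tolerance = 1e-12)
    expect_equal(st$p[1], 2 * pt(-abs(tExp), 4), tolerance = 1e-12)
    # cross-check against stats::t.test as an independent oracle
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(st$t[1], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(st$p[1], tt$p.value, tolerance = 1e-12)
    # identical replicate sets give t = 0, p = 1
    expect_equal(st$t[2], 0)
    expect_equal(st$p[2], 1)
})

test_that("Welch's variant matches stats::t.test", {
    set.seed(1)
    x <- matrix(rnorm(18), 3, 6)
    x[, 4:6] <- x[, 4:6] * 3 + 1
    m <- signalFromMatrix(x)
    st <- perBinTest(m, varEqual = FALSE)
    for (i in 1:3) {
        tt <- t.test(x[i, 4:6], x[i, 1:3])
        expect_equal(st$t[i], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(st$p[i], tt$p.value, tolerance = 1e-10)
    }
})

test_that("degenerate zero-variance bins follow the floor convention", {
    m <- signalFromMatrix(rbind(c(1, 1, 1, 1, 1, 1),
                                c(0, 0, 0, 2, 2, 2)))
    st <- perBinTest(m)
    expect_equal(st$t[1], 0)
    expect_equal(st$p[1], 1)
    # equal variances zero but different means: huge t via the floor
    expect_gt(st$t[2], 1e5)
    expect_lt(st$p[2], 1e-10)
})

test_that("fewer than two replicates per group is an error", {
    m <- signalFromMatrix(matrix(rnorm(8), 2, 4),
                          conditions = c("control", "treated", "treated",
                                         "treated"))
    expect_error(perBinTest(m), "2 replicates")
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
    expect_equal(bhAdjust(c(0.002, 0.01, 0.03, 0.04)),
                 c(0.008, 0.02, 0.04, 0.04))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with an independent brute-force step-up oracle", {
    set.seed(123)
    for (i in 1:25) {
        p <- runif(sample(2:40, 1))^sample(1:3, 1)
        expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
    }
})

test_that("book-ended significant bins merge into single domains", {
    bins <- makeBins(tinyLayout(c(chr1 = 7000)))
    st <- DataFrame(meanDiff = c(1, 1, 1, -1, 0, 1, 1),
                    t = c(9, 9, 9, -9, 0, 9, 9),
                    p = c(1e-5, 1e-5, 1e-5, 1e-5, 0.9, 1e-5, 1e-5),
                    padj = c(1e-4, 1e-4, 1e-4, 1e-4, 0.9, 1e-4, 1e-4),
                    direction = c("up", "up", "up", "down", "up", "up",
                                  "up"))
    res <- callDomains(st, bins, alpha = 0.005, direction = "up")
    d <- domains(res)
    expect_equal(length(d), 2L)
    expect_equal(start(d) - 1L, c(0L, 5000L))
    expect_equal(end(d), c(3000L, 7000L))
    expect_true(all(mcols(d)$direction == "up"))
    # the down bin appears only when asked for
    both <- domains(callDomains(st, bins, direction = "both"))
    expect_equal(length(both), 3L)
    expect_equal(sum(mcols(both)$direction == "down"), 1L)
})

test_that("non-adjacent significant bins stay separate and the empty call
           is clean", {
    bins <- makeBins(tinyLayout(c(chr1 = 6000)))
    padj <- c(1e-4, 0.5, 0.5, 0.5, 0.5, 1e-4)
    st <- DataFrame(meanDiff = rep(1, 6), t = rep(9, 6),
                    p = padj, padj = padj, direction = rep("up", 6))
    res <- callDomains(st, bins)
    expect_equal(length(domains(res)), 2L)

    none <- DataFrame(meanDiff = rep(1, 6), t = rep(1, 6),
                      p = rep(0.5, 6), padj = rep(0.9, 6),
                      direction = rep("up", 6))
    res0 <- callDomains(none, bins)
    expect_equal(length(domains(res0)), 0L)
    expect_equal(domainSummary(res0)$n_domains, 0L)
    expect_error(callDomains(st, bins, alpha = 1.5), "alpha")
})

test_that("domain summaries report count, mean length and workspace
           fraction", {
    bins <- makeBins(tinyLayout(c(chr1 = 10000)))
    padj <- c(1e-4, 1e-4, 0.9, 0.9, 0.9, 1e-4, 0.9, 0.9, 0.9, 0.9)
    st <- DataFrame(meanDiff = rep(1, 10), t = rep(9, 10), p = padj,
                    padj = padj, direction = rep("up", 10))
    res <- callDomains(st, bins)
    ws <- GRanges("chr1", IRanges(1, 1e6))
    s <- summarizeDomains(res, ws)
    expect_equal(s$n_domains, 2L)
    expect_equal(s$mean_length_bp, 1500)
    expect_equal(s$genome_fraction, 3000 / 1e6)
    # empty call: flagged undefined mean, zero fraction
    none <- DataFrame(meanDiff = rep(1, 10), t = rep(0, 10),
                      p = rep(1, 10), padj = rep(1, 10),
                      direction = rep("up", 10))
    s0 <- summarizeDomains(callDomains(none, bins), ws)
    expect_true(is.na(s0$mean_length_bp))
    expect_equal(s0$genome_fraction, 0)
})

test_that("domains are recovered in the detectable-effect regime", {
    # strong induction over 2-bin domains: the caller localises essentially
    # every planted domain to within the smoothing displacement
    b <- runSyntheticBenchmark(seed = 42, nBins = 6000, nDomains = 40,
                               domainLengthBins = 2L, effect = 10,
                               nSim = 50, classify = FALSE)
    r <- b$report$recovery
    expect_gte(r$sensitivity, 0.9)
    expect_gte(r$precision, 0.9)
})

test_that("recovered-domain counts increase with the planted effect", {
    nRec <- vapply(c(2, 6, 12), function(eff) {
        mean(vapply(1:2, function(s) {
            b <- runSyntheticBenchmark(seed = s, nBins = 5000,
                                       nDomains = 30, effect = eff,
                                       nSim = 50, classify = FALSE)
            b$report$recovery$sensitivity * 30
        }, numeric(1)))
    }, numeric(1))
    expect_true(nRec[1] <= nRec[2] && nRec[2] <= nRec[3])
    expect_gt(nRec[3], nRec[1])
})
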