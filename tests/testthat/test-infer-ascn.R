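seg1 <- function(n = 1e5) GRanges("chr1", IRanges(1, n))

snvDf <- function(ta, tb, na, nb, pos = seq_along(ta) * 10)
    data.frame(chrom = "chr1", pos = pos, tumor_a = ta, tumor_b = tb,
               normal_a = na, normal_b = nb)

test_that("LAR is the log ratio of allelic ratios with zero exclusion", {
    snvs <- snvDf(ta = c(10, 15, 12), tb = c(10, 5, 0),
                  na = c(10, 10, 6), nb = c(10, 10, 6))
    sl <- computeLAR(snvs, seg1(), minDepth = 4)[[1]]
    expect_equal(sl$lars, c(0, log(3)))
    expect_equal(sl$nExcludedZero, 1L)
    expect_equal(sl$nRetained, 2L)
    # low-depth exclusion is counted separately from zero exclusion
    snvs2 <- snvDf(ta = c(2, 10), tb = c(1, 10), na = c(2, 10),
                   nb = c(1, 10))
    sl2 <- computeLAR(snvs2, seg1(), minDepth = 4)[[1]]
    expect_equal(sl2$nRetained, 1L)
    expect_equal(sl2$nExcludedZero, 0L)
})

test_that("expected major fraction follows the dosage algebra", {
    expect_equal(expectedMajorFraction(2, 2, 0.3), 0.5)
    expect_equal(expectedMajorFraction(5, 5, 0.9), 0.5)
    expect_equal(expectedMajorFraction(2, 1, 0.5), 0.6)
    expect_equal(expectedMajorFraction(1, 0, 1), 1.0)
    expect_error(expectedMajorFraction(0, 0, 1), "degenerate")
})

test_that("corrected LAR mean matches exact truncated enumeration", {
    # balanced fraction: symmetric truncation, mean exactly 0
    expect_equal(correctedLarMean(0.5, c(4, 7, 9), c(5, 6)), 0)
    # f = 0.75, tumor depth 4, normal term zero by symmetry:
    # E[ln(X / (4 - X)) | 1 <= X <= 3] with X ~ Bin(4, 0.75)
    px <- dbinom(1:3, 4, 0.75)
    manual <- sum(px * log((1:3) / (3:1))) / sum(px)
    expect_equal(correctedLarMean(0.75, 4, 4), manual)
    expect_equal(manual, 0.6061, tolerance = 1e-4)
    # truncation pulls the mean toward zero relative to the naive logit at
    # low depth (at larger n the convexity of the log-odds reverses it)
    for (n in c(4, 5, 6))
        expect_lt(correctedLarMean(0.75, n, 50), log(0.75 / 0.25))
    expect_error(correctedLarMean(1, 5, 5), class = "larSaturated")
    expect_error(correctedLarMean(0, 5, 5), class = "larSaturated")
})

test_that("corrected LAR mean agrees with Monte Carlo within 3 SE", {
    set.seed(19)
    for (i in 1:4) {
        f <- runif(1, 0.55, 0.9)
        n <- sample(4:12, 1)
        x <- rbinom(1e6, n, f)
        x <- x[x >= 1 & x <= n - 1]
        mc <- mean(log(x / (n - x)))
        se <- sd(log(x / (n - x))) / sqrt(length(x))
        expect_lt(abs(correctedLarMean(f, n, 50) - mc), 3 * se + 1e-9)
    }
})

test_that("MACN fitting recovers designed allele splits", {
    set.seed(33)
    simSeg <- function(M, m, p, cov = 5, n = 3000) {
        tcn <- M + m
        f <- expectedMajorFraction(M, m, p)
        dt <- rpois(n, cov * (p * tcn + 2 * (1 - p)) / 2)
        dn <- rpois(n, cov)
        fl <- ifelse(runif(n) < 0.5, 1 - f, f)
        ta <- rbinom(n, dt, fl)
        na <- rbinom(n, dn, 0.5)
        computeLAR(snvDf(ta, dt - ta, na, dn - na), seg1())[[1]]
    }
    # balanced het segment
    r <- fitMACN(simSeg(1, 1, 0.5), 2, 0.5)
    expect_equal(c(r$macn, r$mcn), c(1, 1))
    # copy-neutral LOH at moderate purity
    r <- fitMACN(simSeg(2, 0, 0.5), 2, 0.5)
    expect_equal(c(r$macn, r$mcn), c(2, 0))
    # complete LOH in a pure tumor: decided by the exclusion mass
    r <- fitMACN(simSeg(1, 0, 1), 1, 1)
    expect_equal(c(r$macn, r$mcn), c(1, 0))
    # tcn 3 admits only (2,1) and (3,0)
    r <- fitMACN(simSeg(2, 1, 0.6), 3, 0.6)
    expect_true(r$macn %in% c(2, 3))
    expect_equal(r$macn + r$mcn, 3)
    expect_equal(c(r$macn, r$mcn), c(2, 1))
})

test_that("allele-label symmetry: negating LARs leaves the call unchanged", {
    set.seed(44)
    p <- 0.4
    f <- expectedMajorFraction(3, 1, p)
    n <- 1500
    dt <- rpois(n, 10); dn <- rpois(n, 5)
    fl <- ifelse(runif(n) < 0.5, 1 - f, f)
    ta <- rbinom(n, dt, fl); na <- rbinom(n, dn, 0.5)
    sl <- computeLAR(snvDf(ta, dt - ta, na, dn - na), seg1())[[1]]
    r1 <- fitMACN(sl, 4, p)
    sl$lars <- -sl$lars
    r2 <- fitMACN(sl, 4, p)
    expect_equal(r1$macn, r2$macn)
    expect_equal(r1$mcn, r2$mcn)
})

test_that("segments with too few informative SNVs get no MACN", {
    sl <- list(lars = rep(0.1, 5), tumorDepths = rep(8, 5),
               normalDepths = rep(8, 5), allTumorDepths = rep(8, 5),
               allNormalDepths = rep(8, 5), allZero = rep(FALSE, 5),
               nExcludedZero = 0L, nRetained = 5L)
    r <- fitMACN(sl, 2, 0.5, minSnvs = 20)
    expect_true(is.na(r$macn))
})

test_that("MACN assignment is restricted to clonal segments", {
    calls <- GRanges("chr1", IRanges(c(1, 50001), c(50000, 100000)))
    mcols(calls) <- S4Vectors::DataFrame(
        mean_tre = c(1, 1.2), n_bins = c(50L, 50L),
        tcn_float = c(2, 3.4), tcn_int = c(2L, NA),
        clonal = c(TRUE, FALSE), macn = NA_real_, mcn = NA_real_)
    set.seed(3)
    n <- 400
    dt <- rpois(n, 10); dn <- rpois(n, 10)
    ta <- rbinom(n, dt, 0.5); na <- rbinom(n, dn, 0.5)
    snvs <- snvDf(ta, dt - ta, na, dn - na,
                  pos = round(seq(1, 99000, length.out = n)))
    out <- assignMACN(calls, snvs, p = 0.5)
    expect_false(is.na(out$macn[1]))
    expect_true(is.na(out$macn[2]))     # subclonal: no allele split
    expect_warning(assignMACN(calls, snvs, p = 0.2, tumorContent = 0.4),
                   "tumor content")
})
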