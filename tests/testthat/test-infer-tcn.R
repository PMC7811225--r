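test_that("expected TRE follows the lattice", {
    expect_equal(expectedTRE(2, 0.7, 2), 1.0)
    expect_equal(expectedTRE(3, 0.5, 2), 1.25)
    expect_equal(expectedTRE(0, 1, 2), 0.0)
    # linear form 1 + delta (c - pi)
    p <- 0.37; pi <- 2.8
    d <- p / (p * pi + 2 * (1 - p))
    expect_equal(expectedTRE(0:8, p, pi), 1 + d * (0:8 - pi))
})

test_that("purity inversion round-trips through the lattice relation", {
    expect_equal(purityFromPeriod(0.25, 2), 0.5)
    expect_equal(purityFromPeriod(0.5, 2), 1.0)
    expect_equal(purityFromPeriod(0.1, 2), 0.2)
    set.seed(5)
    for (i in 1:200) {
        p <- runif(1, 0.01, 1)
        pi <- runif(1, 1, 6)
        d <- p / (p * pi + 2 * (1 - p))
        expect_equal(purityFromPeriod(d, pi), p, tolerance = 1e-12)
    }
    expect_error(purityFromPeriod(0.9, 6), class = "invalidPurity")
})

test_that("EM recovers a noiseless lattice to machine precision", {
    p <- 0.6; pi <- 2
    d <- p / (p * pi + 2 * (1 - p))     # 0.3
    cs <- c(0, 1, 2, 2, 3, 4, 2, 5, 2)
    segs <- data.frame(mean_tre = 1 + d * (cs - pi),
                       n_bins = c(200, 400, 5000, 3000, 600, 300, 4000,
                                  150, 2500))
    fit <- emFit(segs, deltaInit = d * 1.05, piInit = 2.1)
    expect_equal(fit@delta, d, tolerance = 1e-9)
    expect_equal(fit@purity, p, tolerance = 1e-8)
    expect_true(fit@converged)
})

test_that("EM log-likelihood is non-decreasing", {
    set.seed(8)
    p <- 0.45; pi <- 2.4
    d <- p / (p * pi + 2 * (1 - p))
    cs <- sample(0:6, 40, replace = TRUE, prob = c(1, 2, 8, 2, 2, 1, 1))
    L <- sample(100:3000, 40, replace = TRUE)
    segs <- data.frame(mean_tre = 1 + d * (cs - pi) + rnorm(40, 0, 0.01),
                       n_bins = L)
    fit <- emFit(segs, d * 1.1, pi + 0.3)
    expect_true(fit@trace$monotone)
    expect_true(all(diff(fit@trace$logLik) > -1e-6))
})

test_that("initializing at a harmonic scores below the true period", {
    p <- 0.5; pi <- 2
    d <- p / (p * pi + 2 * (1 - p))     # 0.25
    cs <- c(1, 2, 3, 2, 4, 5, 2, 6, 7, 2, 8, 3)
    segs <- data.frame(mean_tre = 1 + d * (cs - pi),
                       n_bins = rep(1000, length(cs)))
    fTrue <- emFit(segs, d, pi)
    fHarm <- emFit(segs, 2 * d, pi)
    expect_gt(fTrue@logLik, fHarm@logLik)
    expect_lt(fTrue@bic, fHarm@bic)
})

test_that("model selection minimizes BIC with documented tie-breaks", {
    mkFit <- function(bic, pi, delta = 0.2) {
        p <- 2 * delta / (1 + 2 * delta - delta * pi)
        new("CopyNumberFit", purity = p, ploidy = pi, delta = delta,
            sigma = 0.1, theta = rep(1 / 9, 9), logLik = -bic / 2,
            bic = bic, nParams = 12L, converged = TRUE, nBins = 1e4,
            nSegments = 30L, trace = list())
    }
    f1 <- mkFit(100, 2.5); f2 <- mkFit(120, 2.0)
    expect_equal(selectModel(list(f1, f2))@bic, 100)
    expect_equal(selectModel(list(f1))@bic, 100)
    # equal BIC: ploidy nearest 2 wins
    g1 <- mkFit(100, 2.1); g2 <- mkFit(100, 3.9)
    expect_equal(selectModel(list(g2, g1))@ploidy, 2.1)
    # equal BIC and symmetric ploidy: higher purity wins
    h1 <- mkFit(100, 1.8, delta = 0.18); h2 <- mkFit(100, 2.2, delta = 0.22)
    sel <- selectModel(list(h1, h2))
    expect_equal(sel@purity, max(h1@purity, h2@purity))
    expect_error(selectModel(list()), class = "noModel")
})

test_that("near-tied shifted lattices resolve toward a diploid-dominant genome", {
    mkFit <- function(pi, dom) {
        delta <- 0.2
        p <- 2 * delta / (1 + 2 * delta - delta * pi)
        th <- rep(0.02, 9); th[dom + 1] <- 1 - sum(th[-1])
        new("CopyNumberFit", purity = p, ploidy = pi, delta = delta,
            sigma = 0.1, theta = th / sum(th), logLik = -50, bic = 100,
            nParams = 12L, converged = TRUE, nBins = 1e4, nSegments = 30L,
            trace = list(thetaLen = th / sum(th)))
    }
    shifted <- mkFit(1.6, dom = 1)   # ploidy nearer 2, but dominant state 1
    correct <- mkFit(2.6, dom = 2)
    expect_equal(selectModel(list(shifted, correct))@ploidy, 2.6)
})

test_that("TCN calls split clonal and subclonal segments at the tolerance", {
    fit <- new("CopyNumberFit", purity = 0.5, ploidy = 2, delta = 0.25,
               sigma = 0.05, theta = rep(1 / 9, 9), logLik = 0, bic = 0,
               nParams = 12L, converged = TRUE, nBins = 1e4,
               nSegments = 3L, trace = list())
    segs <- GRanges("chr1", IRanges(c(1, 101, 201) * 1000 - 999,
                                    c(100, 200, 300) * 1000))
    # chat = pi + (m - 1) / delta: lattice point, 3.8, and a negative floor
    mcols(segs) <- S4Vectors::DataFrame(
        mean_tre = c(1 + 0.25 * (3 - 2), 1 + 0.25 * (3.8 - 2), 0.2),
        n_bins = c(100L, 100L, 100L))
    calls <- callTCN(fit, segs, clonalTol = 0.2)
    expect_equal(calls$tcn_int[1], 3L)
    expect_true(calls$clonal[1])
    expect_equal(calls$tcn_float[2], 3.8)
    expect_false(calls$clonal[2])
    expect_true(is.na(calls$tcn_int[2]))
    expect_gte(calls$tcn_float[3], 0)    # floored at zero
})
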