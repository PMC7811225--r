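test_that("the tridiagonal identities behind the SBL core are exact", {
    # dense verification of the machinery .sblCore relies on
    set.seed(4)
    n <- 15L
    F <- outer(1:n, 1:(n - 1), function(i, j) as.numeric(i >= j + 1))
    G <- t(F) %*% F
    expect_equal(G, outer(1:(n - 1), 1:(n - 1),
                          function(j, k) n - pmax(j, k)))
    jset <- sort(sample(n - 1, 6))
    q <- length(jset)
    Ts <- solve(G[jset, jset])
    g <- c(diff(jset), n - jset[q])
    expect_equal(diag(Ts), 1 / g + c(0, 1 / g[-q]))
    expect_equal(Ts[cbind(1:(q - 1), 2:q)], -1 / g[-q])
    # Woodbury posterior identity
    s2 <- 0.17
    alpha <- exp(rnorm(q))
    M <- G[jset, jset] / s2 + diag(alpha)
    K <- diag(1 / alpha) + s2 * Ts
    z <- rnorm(q)
    v <- solve(K, z / alpha)
    expect_equal(c(solve(M, z / s2)), (z - v) / (s2 * alpha))
    expect_equal(diag(solve(M)),
                 1 / alpha - diag(solve(K)) / alpha^2)
})

test_that("constant signals yield no breakpoints", {
    f <- sblFit(rep(2.5, 200), sigma = 0.1)
    expect_length(f$breakpoints, 0L)
})

test_that("a noiseless step is located exactly", {
    y <- c(rep(0, 30), rep(1, 30))
    f <- sblFit(y, sigma = 0.05)
    bp <- backwardEliminate(y, f$breakpoints, tMin = 4, minSegBins = 5,
                            sigma = 0.05)
    expect_equal(bp, 30L)
})

test_that("noisy steps are recovered within one bin at SNR >= 5", {
    set.seed(9)
    y <- c(rep(0, 40), rep(1, 35), rep(-0.5, 45)) + rnorm(120, 0, 0.2)
    f <- sblFit(y, sigma = 0.2)
    bp <- backwardEliminate(y, f$breakpoints, tMin = 4, minSegBins = 5,
                            sigma = 0.2)
    expect_equal(length(bp), 2L)
    expect_lte(abs(bp[1] - 40), 1)
    expect_lte(abs(bp[2] - 75), 1)
})

test_that("SBL rejects malformed signals", {
    expect_error(sblFit(c(1, NA, 2)), "non-finite")
    expect_error(sblFit(numeric(1)), "length")
})

test_that("backward elimination matches exhaustive least squares on small signals", {
    set.seed(21)
    for (rep in 1:5) {
        n <- 60L
        k <- sample(15:45, 1)
        y <- c(rep(0, k), rep(1.2, n - k)) + rnorm(n, 0, 0.25)
        f <- sblFit(y, sigma = 0.25)
        bp <- backwardEliminate(y, f$breakpoints, tMin = 4, minSegBins = 3,
                                sigma = 0.25)
        oracle <- bruteBreakpoints(y, 1)
        expect_equal(length(bp), 1L)
        expect_equal(bp, oracle)
    }
})

test_that("elimination is a fixed point above threshold and empties at t = Inf", {
    y <- c(rep(0, 50), rep(2, 50))
    expect_equal(backwardEliminate(y, 50L, tMin = 4, minSegBins = 5,
                                   sigma = 0.1), 50L)
    expect_length(backwardEliminate(y, c(20L, 50L, 80L), tMin = Inf,
                                    minSegBins = 1, sigma = 0.1), 0L)
})

test_that("raising the threshold only removes breakpoints", {
    set.seed(13)
    y <- c(rep(0, 50), rep(0.6, 50), rep(1.8, 60)) + rnorm(160, 0, 0.3)
    f <- sblFit(y, sigma = 0.3)
    bps <- lapply(c(2, 4, 8, 16), function(t)
        backwardEliminate(y, f$breakpoints, tMin = t, minSegBins = 1,
                          sigma = 0.3))
    for (i in 2:length(bps))
        expect_true(all(bps[[i]] %in% bps[[i - 1]]))
})

test_that("genome segmentation recovers truth boundaries and conserves mass", {
    lay <- tinyLayout()
    truth <- makeTruthProfile(lay, seed = 31)
    sim <- simulatePair(truth, 50, 1, nSnvs = 100, seed = 31)
    tre <- computeTRE(sim$coverage)
    sm <- smoothTRE(tre)
    segs <- segmentGenome(sm)
    # segments never span chromosomes, tile the usable genome disjointly
    expect_true(isDisjoint(segs))
    # mean conservation: sum n_bins * mean_tre = sum usable tre
    expect_equal(sum(segs$n_bins * segs$mean_tre),
                 sum(sm$tre[sm$usable], na.rm = TRUE))
    # every truth boundary has a recovered breakpoint within the
    # smoothing bandwidth (3 bins): kernel smoothing blurs each step, so
    # localization cannot be finer than the kernel sd
    bs <- binSize(lay)
    for (chr in seqlevels(truth)) {
        tb <- truth[seqnames(truth) == chr]
        if (length(tb) == 0) next
        bounds <- sort(unique(c(start(tb) - 1, end(tb))))
        segBounds <- end(segs[seqnames(segs) == chr])
        bounds <- bounds[bounds > bs &
                         bounds < seqlengths(lay@seqinfo)[chr] - bs]
        for (b in bounds)
            expect_lte(min(abs(segBounds - b)), 3 * bs)
    }
})

test_that("constant genomes give one segment per chromosome", {
    lay <- tinyLayout()
    truth <- makeTruthProfile(lay, cnaDesign(nCna = 0), seed = 1)
    sim <- simulatePair(truth, 10, 0, nSnvs = 100, seed = 8)
    segs <- segmentGenome(smoothTRE(computeTRE(sim$coverage)))
    expect_equal(length(segs), 3L)
})

test_that("segmentation honours the usable mask per chromosome", {
    lay <- tinyLayout()
    bins <- layoutBins(lay)
    tre <- rep(1, length(bins))
    usable <- as.character(seqnames(bins)) == "chr2"
    mcols(bins) <- S4Vectors::DataFrame(tre = tre, usable = usable)
    pr <- new("TREProfile", bins)
    segs <- segmentGenome(pr)
    expect_true(all(as.character(seqnames(segs)) == "chr2"))
})
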