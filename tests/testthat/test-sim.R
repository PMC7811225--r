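test_that("default truth profile reproduces the design constraints", {
    lay <- scaledGenomeLayout()
    G <- genomeLength(lay)
    for (seed in c(1, 7, 23)) {
        truth <- makeTruthProfile(lay, seed = seed)
        expect_length(truth, 21L)
        expect_true(isDisjoint(truth))
        frac <- sum(as.numeric(width(truth))) / G
        expect_lt(abs(frac - 0.28), 0.01)
        lenFrac <- width(truth) / G
        expect_true(all(lenFrac >= 5e6 / 3e9 - 1e-9))
        expect_true(all(lenFrac <= 135e6 / 3e9 + 1e-9))
        expect_true(all(truth$tcn %in% c(0:8)))
        expect_true(all(truth$tcn != 2))
        expect_true(all(truth$macn >= truth$mcn))
        expect_true(all(truth$mcn >= 0))
        expect_equal(truth$macn + truth$mcn, truth$tcn)
    }
})

test_that("truth profile generation is deterministic given the seed", {
    lay <- tinyLayout()
    t1 <- makeTruthProfile(lay, seed = 3)
    t2 <- makeTruthProfile(lay, seed = 3)
    t3 <- makeTruthProfile(lay, seed = 4)
    expect_identical(as.data.frame(t1), as.data.frame(t2))
    expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("a zero-CNA config yields an all-diploid genome", {
    lay <- tinyLayout()
    truth <- makeTruthProfile(lay, cnaDesign(nCna = 0), seed = 1)
    expect_length(truth, 0L)
    full <- fullTruthSegments(truth)
    expect_equal(sum(as.numeric(width(full))), genomeLength(lay))
    expect_true(all(full$tcn == 2))
})

test_that("infeasible CNA designs fail with an informative error", {
    lay <- miniLayout(1e5)   # 100 kb genome cannot host 21 Mb-scale CNAs
    expect_error(makeTruthProfile(lay, cnaDesign(), seed = 1),
                 "infeasible|placement")
})

test_that("subclone mixing averages copy numbers by fraction", {
    lay <- miniLayout(1e5)
    mk <- function(tcn, macn) {
        gr <- GRanges("chr1", IRanges(20001, 60000),
                      seqinfo = lay@seqinfo)
        mcols(gr) <- S4Vectors::DataFrame(
            tcn = tcn, macn = macn, mcn = tcn - macn, clonal = TRUE)
        out <- new("TruthProfile", gr)
        S4Vectors::metadata(out) <- list(layout = lay)
        out
    }
    # the designed two-subclone example: 0.6 * 2 + 0.4 * 7 = 4
    mixed <- mixSubclones(list(mk(2, 1), mk(7, 4)), c(0.6, 0.4))
    reg <- mixed[start(mixed) == 20001]
    expect_equal(reg$tcn, 4.0)
    expect_false(reg$clonal)
    # identical subclones pass through unchanged (clonal, same values)
    same <- mixSubclones(list(mk(3, 2), mk(3, 2)), c(0.3, 0.7))
    expect_equal(same$tcn, 3)
    expect_equal(same$macn, 2)
    expect_true(all(same$clonal))
    # 50/50 of copy 1 and 3 averages to 2, flagged subclonal
    half <- mixSubclones(list(mk(1, 1), mk(3, 2)), c(0.5, 0.5))
    reg <- half[start(half) == 20001]
    expect_equal(reg$tcn, 2.0)
    expect_false(reg$clonal)
})

test_that("subclone mixing conserves genome length and rejects bad input", {
    lay <- tinyLayout()
    t1 <- makeTruthProfile(lay, seed = 5)
    mixed <- mixSubclones(list(t1, t1), c(0.5, 0.5))
    expect_equal(sum(as.numeric(width(fullTruthSegments(mixed)))),
                 genomeLength(lay))
    expect_error(mixSubclones(list(t1, t1), c(0.5, 0.2)), "sum to 1")
    other <- makeTruthProfile(miniLayout(2e6), cnaDesign(nCna = 0), seed = 1)
    expect_error(mixSubclones(list(t1, other), c(0.5, 0.5)),
                 "different genome layouts")
})

test_that("two-subclone designs differ in the requested regions", {
    lay <- tinyLayout()
    mixed <- twoSubcloneTruth(lay, seed = 2)
    expect_false(all(mixed$clonal))
    designed <- S4Vectors::metadata(mixed)$designedRegion
    hit <- findOverlaps(designed, mixed, select = "first")
    expect_equal(mixed$tcn[hit], 4.0)   # 0.6 * 2 + 0.4 * 7
    expect_false(mixed$clonal[hit])
})

test_that("simulated counts follow the purity-scaled Poisson model", {
    lay <- tinyLayout()
    truth <- makeTruthProfile(lay, seed = 9)
    # purity 0: tumor is distributed like the normal (equal per-bin rates)
    sim0 <- simulatePair(truth, 5, 0, nSnvs = 1000, seed = 1)
    expect_lt(abs(mean(sim0$coverage$tumor_count) -
                  mean(sim0$coverage$normal_count)),
              3 * sd(sim0$coverage$normal_count) / sqrt(length(sim0$coverage)))
    # purity 1, a tcn 4 region: tumor mean = 2 x normal mean
    sim1 <- simulatePair(truth, 10, 1, nSnvs = 1000, seed = 2)
    reg4 <- truth[truth$tcn == 4]
    if (length(reg4) > 0) {
        inReg <- overlapsAny(granges(sim1$coverage), reg4[1])
        ratio <- mean(sim1$coverage$tumor_count[inReg]) /
            mean(sim1$coverage$normal_count[inReg])
        expect_lt(abs(ratio - 2), 0.15)
    }
    # genome-wide depth ratio converges to (p pi + 2 (1 - p)) / 2
    p <- 0.6
    sim <- simulatePair(truth, 10, p, nSnvs = 1000, seed = 3)
    full <- fullTruthSegments(truth)
    piBar <- sum(width(full) * full$tcn) / sum(as.numeric(width(full)))
    expRatio <- (p * piBar + 2 * (1 - p)) / 2
    obs <- sum(sim$coverage$tumor_count) / sum(sim$coverage$normal_count)
    n <- length(sim$coverage)
    lam <- mean(sim$coverage$normal_count)
    se <- expRatio * sqrt(2 / (n * lam))   # delta-method, generous
    expect_lt(abs(obs - expRatio), 3 * se)
})

test_that("simulatePair is deterministic and validates purity", {
    lay <- tinyLayout()
    truth <- makeTruthProfile(lay, seed = 4)
    a <- simulatePair(truth, 5, 0.5, nSnvs = 500, seed = 77)
    b <- simulatePair(truth, 5, 0.5, nSnvs = 500, seed = 77)
    expect_identical(a$snvs, b$snvs)
    expect_identical(as.data.frame(a$coverage), as.data.frame(b$coverage))
    expect_error(simulatePair(truth, 5, 1.2, seed = 1), "purity")
})

test_that("LOH segments in a pure tumor lose the minor allele entirely", {
    lay <- miniLayout(2e6)
    gr <- GRanges("chr1", IRanges(1, 2e6), seqinfo = lay@seqinfo)
    mcols(gr) <- S4Vectors::DataFrame(tcn = 2, macn = 2, mcn = 0,
                                      clonal = TRUE)
    truth <- new("TruthProfile", gr)
    S4Vectors::metadata(truth) <- list(layout = lay)
    sim <- simulatePair(truth, 20, 1, nSnvs = 2000, seed = 5)
    minor <- pmin(sim$snvs$tumor_a, sim$snvs$tumor_b)
    expect_true(all(minor == 0))
})
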