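suppressPackageStartupMessages(library(GenomicRanges))

# small multi-chromosome layout for fast end-to-end tests (30 Mb, 1 kb bins)
tinyLayout <- function(binSize = 1000L)
    genomeLayout(c(chr1 = 12e6, chr2 = 10e6, chr3 = 8e6), binSize)

# one-chromosome layout for unit tests
miniLayout <- function(len = 2e5, binSize = 1000L)
    genomeLayout(c(chr1 = len), binSize)

# BinnedCoverage from explicit count vectors on a mini layout
makeCoverage <- function(tumor, normal, binSize = 1000L) {
    lay <- genomeLayout(c(chr1 = length(tumor) * binSize), binSize)
    bins <- layoutBins(lay)
    mcols(bins) <- S4Vectors::DataFrame(tumor_count = as.integer(tumor),
                                        normal_count = as.integer(normal))
    cov <- new("BinnedCoverage", bins)
    S4Vectors::metadata(cov) <- list(layout = lay)
    cov
}

# TREProfile from an explicit tre vector (all usable unless masked)
makeTreProfile <- function(tre, usable = rep(TRUE, length(tre)),
                           binSize = 1000L, smoothed = FALSE) {
    lay <- genomeLayout(c(chr1 = length(tre) * binSize), binSize)
    bins <- layoutBins(lay)
    mcols(bins) <- S4Vectors::DataFrame(tre = tre, usable = usable)
    pr <- new("TREProfile", bins)
    S4Vectors::metadata(pr) <- list(smoothed = smoothed)
    pr
}

# exhaustive least-squares breakpoint search (oracle for the segmenter):
# best set of k breakpoints minimizing within-segment SSE
bruteBreakpoints <- function(y, k) {
    n <- length(y)
    sse <- function(idx) sum((y[idx] - mean(y[idx]))^2)
    if (k == 0) return(integer(0))
    if (k == 1) {
        costs <- vapply(1:(n - 1), function(b)
            sse(1:b) + sse((b + 1):n), 0.0)
        return(which.min(costs))
    }
    best <- NULL; bestCost <- Inf
    for (b1 in 1:(n - 2)) for (b2 in (b1 + 1):(n - 1)) {
        cost <- sse(1:b1) + sse((b1 + 1):b2) + sse((b2 + 1):n)
        if (cost < bestCost) { bestCost <- cost; best <- c(b1, b2) }
    }
    best
}

# brute-force per-base FullC (oracle for the sweep implementation); genomes
# small enough to materialize one value per bp
bruteFullC <- function(truth, pred, genomeLen, normalValue = 2) {
    tv <- rep(NA_real_, genomeLen)
    for (i in seq_along(truth))
        tv[start(truth)[i]:end(truth)[i]] <- truth$tcn[i]
    pv <- rep(NA_real_, genomeLen)
    for (j in seq_along(pred))
        pv[start(pred)[j]:end(pred)[j]] <- pred$tcn[j]
    keep <- !is.na(tv) & !is.na(pv) &
        !(tv == normalValue & pv == normalValue)
    if (!any(keep)) return(NA_real_)
    sum(exp(-abs(tv[keep] - pv[keep]))) / sum(keep)
}

# truth profile + simulated pair on the tiny layout, shared across tests
quickSim <- function(coverage = 5, purity = 0.5, seed = 11,
                     nSnvs = 2e4L, layout = tinyLayout()) {
    truth <- makeTruthProfile(layout, seed = seed)
    sim <- simulatePair(truth, coverage, purity, nSnvs, seed = seed + 500L)
    list(layout = layout, truth = truth, cov = sim$coverage,
         snvs = sim$snvs)
}
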