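#' Segmentation parameters
#'
#' @param sblA hierarchical-prior hyperparameter of the sparse Bayesian
#'   learning stage; larger values prune breakpoints more aggressively.
#' @param tMin backward-elimination threshold on the breakpoint t statistic.
#' @param minSegBins minimum segment length in usable bins; shorter segments
#'   are merged into the more similar neighbour.
#' @param maxIter,tol SBL iteration cap and convergence tolerance on the
#'   maximum breakpoint-weight change.
#' @param alphaMax pruning cap on the SBL precision hyperparameters.
#' @return list of class \code{segmentationParams}.
#' @export
segmentationParams <- function(sblA = 0.2, tMin = 4.0, minSegBins = 10L,
                               maxIter = 10000L, tol = 1e-8,
                               alphaMax = 1e12) {
    stopifnot(sblA > 0, tMin > 0, minSegBins >= 1)
    structure(list(sblA = sblA, tMin = tMin,
                   minSegBins = as.integer(minSegBins),
                   maxIter = as.integer(maxIter), tol = tol,
                   alphaMax = alphaMax),
              class = "segmentationParams")
}

#' Sparse-Bayesian-learning fit of the step basis
#'
#' Fits y = beta0 + F w + e where column j of the step basis F is the unit
#' step after position j, with zero-mean Gaussian priors on the w whose
#' precisions carry a Gamma hyperprior (GADA stage 1). Most weights are
#' driven to exactly zero; the survivors are breakpoint proposals for
#' \code{\link{backwardEliminate}}.
#'
#' @param signal numeric vector (one chromosome, missing bins removed).
#' @param params \code{\link{segmentationParams}}.
#' @param sigma noise sd of the signal; estimated as
#'   \code{mad(diff(signal))/sqrt(2)} when NULL.
#' @return list with \code{w} (breakpoint weights, length
#'   \code{length(signal) - 1}), \code{alpha}, \code{breakpoints} (positions
#'   j of surviving steps: segment boundary between j and j+1), \code{beta0},
#'   \code{sigma}, \code{iterations}, \code{converged}.
#' @export
sblFit <- function(signal, params = segmentationParams(), sigma = NULL) {
    if (length(signal) < 2) stop("signal must have length >= 2")
    if (any(!is.finite(signal))) stop("non-finite values in signal")
    if (is.null(sigma)) sigma <- mad(diff(signal)) / sqrt(2)
    sigma <- max(sigma, 1e-8)
    fit <- .sblCore(as.numeric(signal), params$sblA, sigma^2, params$tol,
                    params$maxIter, params$alphaMax)
    fit$sigma <- sigma
    fit$breakpoints <- fit$active[abs(fit$w[fit$active]) > 1e-10]
    fit
}

# segment means given breakpoints (positions after which a new segment starts)
.segMeans <- function(y, bp) {
    starts <- c(1L, bp + 1L)
    ends <- c(bp, length(y))
    list(starts = starts, ends = ends,
         len = ends - starts + 1L,
         mean = vapply(seq_along(starts), function(i)
             mean(y[starts[i]:ends[i]]), 0.0))
}

# t statistic of each breakpoint: mean difference across it, scaled by the
# per-bin noise sd and the lengths of the flanking segments. TRE is a ratio
# of Poisson counts, so its sampling variance grows with its level --
# Var(TRE) ~ TRE (1 + TRE) / 2 relative to the variance at TRE = 1, where
# sigma is estimated; without the level factor, high-copy regions are
# systematically over-split and homozygous-deletion regions under-split
.bpLevelVar <- function(m) {
    m <- pmax(m, 0.05)
    m * (1 + m) / 2
}

.bpStats <- function(y, bp, sigma, levelVar = FALSE) {
    if (length(bp) == 0) return(numeric(0))
    s <- .segMeans(y, bp)
    k <- seq_along(bp)
    v <- if (levelVar) .bpLevelVar(s$mean) else rep(1, length(s$mean))
    abs(s$mean[k + 1] - s$mean[k]) /
        (sigma * sqrt(v[k] / s$len[k] + v[k + 1] / s$len[k + 1]))
}

#' Backward elimination of weak breakpoints (GADA stage 2)
#'
#' Iteratively removes the breakpoint with the smallest t statistic
#' until every remaining breakpoint satisfies t >= tMin, then merges
#' segments shorter than \code{minSegBins} into the neighbour with the
#' closer mean.
#'
#' @param signal numeric vector.
#' @param breakpoints integer positions (boundary between j and j+1).
#' @param tMin threshold on the breakpoint statistic.
#' @param minSegBins minimum surviving segment length.
#' @param sigma per-bin noise sd used in the t statistics (at signal
#'   level 1 when \code{levelVar} is on).
#' @param levelVar scale the variance with the local signal level as for a
#'   Poisson count ratio (Var proportional to m (1 + m) / 2). Appropriate
#'   for TRE tracks, where the noise grows with the copy number; off by
#'   default so the statistic matches the classical homoscedastic form.
#' @return integer vector of surviving breakpoint positions.
#' @export
backwardEliminate <- function(signal, breakpoints, tMin = 4.0,
                              minSegBins = 10L, sigma = NULL,
                              levelVar = FALSE) {
    y <- as.numeric(signal)
    if (is.null(sigma)) sigma <- max(mad(diff(y)) / sqrt(2), 1e-8)
    bp <- sort(unique(as.integer(breakpoints)))
    stopifnot(all(bp >= 1), all(bp < length(y)))
    while (length(bp) > 0) {
        t <- .bpStats(y, bp, sigma, levelVar)
        if (all(t >= tMin)) break
        bp <- bp[-which.min(t)]
    }
    # merge short segments into the more similar neighbour
    repeat {
        if (length(bp) == 0) break
        s <- .segMeans(y, bp)
        short <- which(s$len < minSegBins)
        if (length(short) == 0) break
        i <- short[which.min(s$len[short])]
        leftDiff <- if (i > 1) abs(s$mean[i] - s$mean[i - 1]) else Inf
        rightDiff <- if (i < length(s$mean)) abs(s$mean[i] - s$mean[i + 1])
                     else Inf
        drop <- if (leftDiff <= rightDiff) i - 1L else i
        bp <- bp[-drop]
    }
    bp
}

#' Segment the genome from a smoothed TRE track
#'
#' Runs the sparse-Bayesian-learning fit plus backward elimination on the
#' usable bins of each chromosome independently (segments never span
#' chromosomes). When the track was produced by \code{\link{smoothTRE}}, the
#' t statistics of the elimination stage are computed against the raw
#' (pre-smoothing) per-bin noise scale, recovered from the kernel's variance
#' attenuation, so that the effective test is the one for the unsmoothed
#' segment means.
#'
#' @param profile a \code{\link{TREProfile}} (typically smoothed).
#' @param params \code{\link{segmentationParams}}.
#' @return a \code{GRanges} of segments with metadata columns
#'   \code{mean_tre} (mean of usable smoothed TRE) and \code{n_bins}
#'   (number of usable bins).
#' @export
segmentGenome <- function(profile, params = segmentationParams()) {
    stopifnot(is(profile, "TREProfile"))
    usable <- profile$usable & is.finite(profile$tre)
    if (!any(usable)) stop("no usable bins to segment")
    md <- metadata(profile)
    smoothedCorr <- if (isTRUE(md$smoothed)) {
        kf <- .kernelFactors(md$bandwidthBins,
                             if (is.null(md$truncate)) 4 else md$truncate)
        kf
    } else list(sk2 = 1, rho1 = 0)
    out <- GRanges(seqinfo = seqinfo(profile))
    mcols(out) <- DataFrame(mean_tre = numeric(0), n_bins = integer(0))
    pieces <- list()
    for (chr in seqlevels(profile)) {
        idx <- which(as.character(seqnames(profile)) == chr & usable)
        if (length(idx) == 0) next
        y <- profile$tre[idx]
        if (length(idx) == 1) {
            bp <- integer(0)
        } else {
            # per-bin sd of the smoothed track, mapped back to the raw
            # per-bin scale: smoothing shrinks the pointwise noise but adds
            # no information, so both the SBL likelihood and the
            # elimination t statistics must be calibrated against the raw
            # per-bin sd or every correlated wiggle counts as a step
            sigmaSm <- mad(diff(y)) /
                sqrt(2 * max(1 - smoothedCorr$rho1, 1e-3))
            sigmaSm <- max(sigmaSm, 1e-8)
            sigmaRaw <- sigmaSm / sqrt(smoothedCorr$sk2)
            fit <- sblFit(y, params, sigma = sigmaRaw)
            bp <- backwardEliminate(y, fit$breakpoints, params$tMin,
                                    params$minSegBins, sigma = sigmaRaw,
                                    levelVar = TRUE)
        }
        s <- .segMeans(y, bp)
        gr <- GRanges(chr,
                      IRanges(start(profile)[idx[s$starts]],
                              end(profile)[idx[s$ends]]),
                      seqinfo = seqinfo(profile))
        mcols(gr) <- DataFrame(mean_tre = s$mean, n_bins = s$len)
        pieces[[chr]] <- gr
    }
    sort(do.call(c, unname(pieces)))
}
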