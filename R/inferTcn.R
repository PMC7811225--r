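#' Expected TRE of a copy state
#'
#' Under the lattice model, a clonal segment with total copy number c in a
#' sample of purity p and tumor ploidy \eqn{\pi} has expected TRE
#' \deqn{E[TRE] = \frac{p c + 2 (1 - p)}{p \pi + 2 (1 - p)} =
#'   1 + \Delta (c - \pi)} with lattice spacing
#' \eqn{\Delta = p / (p \pi + 2 (1 - p))}.
#'
#' @param c copy number (vectorized).
#' @param p purity in (0, 1].
#' @param pi tumor ploidy.
#' @return expected TRE value(s).
#' @examples
#' expectedTRE(2, 0.7, 2)   # 1: diploid state is the reference point
#' expectedTRE(3, 0.5, 2)   # 1.25
#' @export
expectedTRE <- function(c, p, pi) {
    stopifnot(p > 0, p <= 1, pi > 0)
    (p * c + 2 * (1 - p)) / (p * pi + 2 * (1 - p))
}

#' Purity implied by a period at a given ploidy
#'
#' Inverts the lattice relation \eqn{\Delta = p / (p \pi + 2 (1 - p))}:
#' \deqn{p = \frac{2 \Delta}{1 + 2 \Delta - \Delta \pi}.}
#' A period/ploidy pair whose implied purity falls outside (0, 1] is not a
#' valid hypothesis and raises an error of class \code{invalidPurity} so
#' that candidate scans can reject it explicitly.
#'
#' @param delta period (TRE lattice spacing), > 0.
#' @param pi tumor ploidy.
#' @return purity in (0, 1].
#' @examples
#' purityFromPeriod(0.25, 2)  # 0.5
#' @export
purityFromPeriod <- function(delta, pi) {
    stopifnot(delta > 0)
    p <- 2 * delta / (1 + 2 * delta - delta * pi)
    if (!is.finite(p) || p <= 0 || p > 1 + 1e-12)
        stop(structure(class = c("invalidPurity", "error", "condition"),
            list(message = sprintf(
                "period %.4g at ploidy %.3g implies purity %.4g outside (0, 1]",
                delta, pi, p), call = sys.call())))
    min(p, 1)
}

#' EM options for the lattice mixture fit
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxIter iteration cap.
#' @param sigmaMin floor on the per-bin noise sd, in TRE units.
#' @param seMin floor on the standard error of a segment mean, in TRE
#'   units: even very long segments carry small systematic deviations from
#'   the lattice (boundary contamination, residual ratio bias), so their
#'   means must not be treated as infinitely precise.
#' @param outlierMax cap on the outlier-component weight; off-lattice
#'   segments are a minority by definition.
#' @return list.
#' @export
emOptions <- function(tol = 1e-6, maxIter = 500L, sigmaMin = 1e-4,
                      seMin = 2e-3, outlierMax = 0.25) {
    list(tol = tol, maxIter = as.integer(maxIter), sigmaMin = sigmaMin,
         seMin = seMin, outlierMax = outlierMax)
}

# log-likelihood of segment means under the lattice mixture
.latticeLogLik <- function(m, L, mu, theta, sigma) {
    # log sum_c theta_c N(m_s; mu_c, sigma^2 / L_s), summed over segments
    se <- sigma / sqrt(L)
    ll <- vapply(seq_along(m), function(s) {
        lp <- log(theta) + dnorm(m[s], mu, se[s], log = TRUE)
        mx <- max(lp)
        mx + log(sum(exp(lp - mx)))
    }, 0.0)
    sum(ll)
}

#' Autocorrelation-guided EM fit of the lattice-tied Gaussian mixture
#'
#' Fits segment mean TREs as draws from a mixture over integer copy states
#' c = 0..cMax with component means tied to the lattice
#' \eqn{\mu_c = 1 + \Delta (c - \pi)} and variances \eqn{\sigma^2 / L_s}
#' scaled by segment size, so long segments weigh more; a uniform outlier
#' component over the observed TRE range absorbs off-lattice segment means
#' (subclonal regions, boundary smear), so they cannot distort the lattice
#' or be captured by a spurious edge component of a shifted lattice. The M
#' step updates the mixture weights in closed form and re-estimates the
#' lattice (intercept and spacing) by responsibility-weighted least
#' squares, which makes the log-likelihood non-decreasing across
#' iterations; ploidy is the lattice point mapped to TRE 1.
#'
#' @param segs segment \code{GRanges} from \code{\link{segmentGenome}}
#'   (columns \code{mean_tre}, \code{n_bins}), or a data.frame with those
#'   columns.
#' @param deltaInit initial period (e.g. a \code{\link{candidatePeriods}}
#'   row).
#' @param piInit initial ploidy.
#' @param cMax largest copy state of the mixture.
#' @param opts \code{\link{emOptions}}.
#' @return a \code{\link{CopyNumberFit}}.
#' @export
emFit <- function(segs, deltaInit, piInit = 2, cMax = 8L,
                  opts = emOptions()) {
    m <- segs$mean_tre
    L <- as.numeric(segs$n_bins)
    stopifnot(length(m) >= 2, all(is.finite(m)), all(L >= 1))
    cs <- 0:cMax
    K <- cMax + 1L
    S <- length(m)
    delta <- deltaInit
    a <- 1 - delta * piInit        # lattice intercept: mu_c = a + delta * c
    theta <- c(rep(0.99 / K, K), 0.01)   # last entry: outlier weight
    logDensOut <- -log(max(diff(range(m)), 1e-3))
    mu <- a + delta * cs
    sigma <- max(sd(m - mu[pmin(pmax(round((m - a) / delta), 0), cMax) + 1]),
                 10 * opts$sigmaMin)
    if (!is.finite(sigma)) sigma <- 0.1
    logL <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    monotone <- TRUE
    for (iter in seq_len(opts$maxIter)) {
        mu <- a + delta * cs
        se <- pmax(sigma / sqrt(L), opts$seMin)
        # E step (responsibilities, log-sum-exp guarded); column K + 1 is
        # the uniform outlier component
        lp <- cbind(outer(seq_len(S), seq_len(K), function(s, k)
            log(theta[k]) + dnorm(m[s], mu[k], se[s], log = TRUE)),
            log(theta[K + 1L]) + logDensOut)
        mx <- apply(lp, 1, max)
        r <- exp(lp - mx)
        rs <- rowSums(r)
        r <- r / rs
        newLogL <- sum(mx + log(rs))
        if (newLogL < logL - 1e-8 * (1 + abs(logL))) monotone <- FALSE
        dL <- newLogL - logL
        logL <- newLogL
        trace <- c(trace, logL)
        if (is.finite(dL) && abs(dL) < opts$tol) { converged <- TRUE; break }
        # M step
        theta <- pmax(colMeans(r), 1e-12)
        theta <- theta / sum(theta)
        if (theta[K + 1L] > opts$outlierMax) {
            theta[K + 1L] <- opts$outlierMax
            theta[seq_len(K)] <- theta[seq_len(K)] /
                sum(theta[seq_len(K)]) * (1 - opts$outlierMax)
        }
        rl <- r[, seq_len(K), drop = FALSE]
        w <- rl * L                      # precision weights of (s, c) pairs
        sw <- sum(w)
        cbar <- sum(t(w) * cs) / sw
        mbar <- sum(rowSums(w) * m) / sw
        sxx <- sum(t(w) * (cs - cbar)^2)
        sxy <- sum(w * outer(m - mbar, cs - cbar, function(mm, cc) mm * cc))
        if (sxx > 0 && sxy > 0) {
            delta <- sxy / sxx
            a <- mbar - delta * cbar
        }
        resid2 <- w * outer(m, mu <- a + delta * cs, `-`)^2
        sigma <- max(sqrt(sum(resid2) / max(sum(rl), 1)), opts$sigmaMin)
    }
    piHat <- (1 - a) / delta
    # genome-mass distribution over copy states (bin-weighted, not
    # segment-count-weighted): used by selectModel to identify the state
    # that occupies most of the genome
    thetaLen <- colSums(r[, seq_len(K), drop = FALSE] * L) / sum(L)
    p <- purityFromPeriod(delta, piHat)    # errors if outside (0, 1]
    deltaTied <- p / (p * piHat + 2 * (1 - p))
    nParams <- as.integer(cMax + 4L)   # cMax + 1 free weights + a, delta, sigma
    bic <- -2 * logL + nParams * log(sum(L))
    new("CopyNumberFit", purity = p, ploidy = piHat, delta = deltaTied,
        sigma = sigma, theta = theta[seq_len(K)] / sum(theta[seq_len(K)]),
        logLik = logL, bic = bic,
        nParams = nParams, converged = converged, nBins = sum(L),
        nSegments = as.integer(S),
        trace = list(logLik = trace, monotone = monotone, thetaLen = thetaLen,
                     thetaOutlier = theta[K + 1L],
                     deltaInit = deltaInit, piInit = piInit))
}

#' Fit the lattice mixture from ranked period candidates
#'
#' For each candidate period, the tallest TRE histogram peak is anchored to
#' copy numbers 1..4 in turn, each anchor implying an initial ploidy
#' (and purity); every admissible initialization is refined by
#' \code{\link{emFit}}. Initializations whose implied purity leaves (0, 1]
#' or whose ploidy leaves \code{ploidyBounds} are rejected. Each ACF
#' candidate is also tried at its sub-multiples delta/2 and delta/3 (when
#' still inside the admissible period range): if the prominent copy states
#' of a genome share a common factor -- e.g. mostly even copy numbers --
#' the strongest ACF peak sits at a multiple of the true lattice spacing,
#' and only the likelihood of the full mixture can tell the two apart.
#'
#' @param segs segment track (see \code{\link{emFit}}).
#' @param candidates data.frame from \code{\link{candidatePeriods}}.
#' @param hist \code{TreHistogram} used for peak anchoring.
#' @param cMax largest copy state.
#' @param ploidyBounds admissible initial ploidy range.
#' @param deltaRange admissible period range (sub-multiples outside it are
#'   not tried).
#' @param opts \code{\link{emOptions}}.
#' @return list of \code{\link{CopyNumberFit}}s (possibly empty).
#' @export
candidateFits <- function(segs, candidates, hist, cMax = 8L,
                          ploidyBounds = c(1.2, 6),
                          deltaRange = deltaBounds(), opts = emOptions()) {
    peak <- hist$centers[which.max(hist$counts)]
    deltas <- unique(unlist(lapply(candidates$delta, function(d) {
        sub <- d / (1:3)
        sub[sub >= deltaRange[1] & sub <= deltaRange[2]]
    })))
    fits <- list()
    tried <- character(0)
    for (d0 in deltas) {
        for (cAnchor in 1:4) {
            pi0 <- cAnchor - (peak - 1) / d0
            if (!is.finite(pi0) || pi0 < ploidyBounds[1] ||
                pi0 > ploidyBounds[2]) next
            key <- sprintf("%.4f|%.2f", d0, pi0)
            if (key %in% tried) next
            tried <- c(tried, key)
            f <- tryCatch(
                emFit(segs, d0, pi0, cMax, opts),
                invalidPurity = function(e) NULL,
                error = function(e) NULL)
            if (!is.null(f)) fits[[length(fits) + 1L]] <- f
        }
    }
    fits
}

#' Select the best model by BIC
#'
#' Returns the minimum-BIC fit. Fits within 2 BIC units of the minimum are
#' statistically indistinguishable; among them the tie is broken first
#' toward the fit whose heaviest mixture component is the diploid state
#' (the lattice model is invariant under shifting every copy assignment by
#' one -- purity and ploidy move together -- unless a copy-0 or copy-cMax
#' segment pins the lattice, and the shifted solutions relabel the most
#' common state of the genome as non-diploid), then toward the ploidy
#' closest to 2, then toward the higher purity. Raises an error of class
#' \code{noModel} when no valid fit exists (typically a sample with little
#' or no copy-number alteration, for which the periodic TRE pattern the
#' model requires does not arise).
#'
#' @param fits list of \code{\link{CopyNumberFit}}s.
#' @return the selected \code{\link{CopyNumberFit}}.
#' @export
selectModel <- function(fits) {
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0)
        stop(structure(class = c("noModel", "error", "condition"),
            list(message = paste("no admissible model fit; the sample may",
                "carry little or no copy-number alteration"),
                call = sys.call())))
    bic <- vapply(fits, function(f) f@bic, 0.0)
    tied <- which(bic - min(bic) <= 2)
    if (length(tied) > 1) {
        dom2 <- vapply(fits[tied], function(f) {
            th <- if (!is.null(f@trace$thetaLen)) f@trace$thetaLen else f@theta
            which.max(th) == 3L              # index 3 <=> copy 2
        }, NA)
        if (any(dom2)) tied <- tied[dom2]
    }
    if (length(tied) > 1) {
        dpi <- vapply(fits[tied], function(f) abs(f@ploidy - 2), 0.0)
        tied <- tied[dpi - min(dpi) <= 1e-9]
        if (length(tied) > 1) {
            pur <- vapply(fits[tied], function(f) f@purity, 0.0)
            tied <- tied[which.max(pur)]
        }
    }
    fits[[tied[1]]]
}

#' Per-segment total copy number calls
#'
#' Maps each segment mean TRE to a continuous copy number
#' \eqn{\hat c_s = \pi + (\bar{TRE}_s - 1) / \Delta} (floored at 0).
#' Segments within \code{clonalTol} of an integer are called clonal and get
#' that integer TCN; the rest are subclonal with the continuous estimate
#' rounded to one decimal, reflecting a copy number averaged across tumor
#' subclones.
#'
#' @param fit a \code{\link{CopyNumberFit}}.
#' @param segs segment track (see \code{\link{emFit}}).
#' @param clonalTol distance to the nearest integer below which a segment is
#'   clonal.
#' @return a \code{GRanges} with columns \code{mean_tre}, \code{n_bins},
#'   \code{tcn_float}, \code{tcn_int} (NA when subclonal), \code{clonal},
#'   \code{macn}, \code{mcn} (NA until \code{\link{assignMACN}}).
#' @export
callTCN <- function(fit, segs, clonalTol = 0.2) {
    chat <- pmax(fit@ploidy + (segs$mean_tre - 1) / fit@delta, 0)
    nearest <- round(chat)
    clonal <- abs(chat - nearest) <= clonalTol
    calls <- granges(segs)
    mcols(calls) <- DataFrame(
        mean_tre = segs$mean_tre, n_bins = segs$n_bins,
        tcn_float = ifelse(clonal, nearest, round(chat, 1)),
        tcn_int = ifelse(clonal, as.integer(nearest), NA_integer_),
        clonal = clonal,
        macn = NA_real_, mcn = NA_real_)
    calls
}
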