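#' Compute Tumor Read Enrichment (TRE)
#'
#' TRE of a bin is the double-normalized depth ratio
#' \deqn{TRE_i = (t_i / R_t) / (n_i / R_n)} where \eqn{t_i, n_i} are the
#' tumor and normal read counts of bin i and \eqn{R_t, R_n} the genome-wide
#' totals. The double normalization makes the normal-count-weighted mean TRE
#' exactly 1 and removes library-size effects, so for a clonal segment of
#' copy number c in a sample of purity p and tumor ploidy \eqn{\pi},
#' \eqn{E[TRE] = (p c + 2 (1 - p)) / (p \pi + 2 (1 - p))}. Bins with normal
#' count below \code{minNormalCount} are flagged unusable and excluded from
#' all downstream computation.
#'
#' @param cov a \code{\link{BinnedCoverage}}.
#' @param minNormalCount minimum normal read count for a usable bin.
#' @return a \code{\link{TREProfile}}.
#' @examples
#' bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(10, 20)))
#' GenomicRanges::mcols(bins) <- S4Vectors::DataFrame(
#'   tumor_count = c(10L, 20L), normal_count = c(10L, 10L))
#' computeTRE(new("BinnedCoverage", bins), minNormalCount = 1)
#' @export
computeTRE <- function(cov, minNormalCount = 5L) {
    stopifnot(is(cov, "BinnedCoverage"))
    tc <- cov$tumor_count
    nc <- cov$normal_count
    Rt <- sum(as.numeric(tc))
    Rn <- sum(as.numeric(nc))
    if (Rt <= 0 || Rn <= 0)
        stop("total tumor and normal read counts must both be positive")
    usable <- nc >= minNormalCount
    tre <- rep(NA_real_, length(cov))
    tre[usable] <- (tc[usable] / Rt) / (nc[usable] / Rn)
    out <- granges(cov)
    mcols(out) <- DataFrame(tre = tre, usable = usable)
    out <- new("TREProfile", out)
    metadata(out) <- c(metadata(cov),
                       list(minNormalCount = minNormalCount,
                            smoothed = FALSE))
    out
}

# gaussian kernel weights truncated at trunc*sigma
.gaussKernel <- function(sigma, trunc = 4) {
    h <- max(1L, ceiling(trunc * sigma))
    k <- dnorm(seq(-h, h), sd = sigma)
    k / sum(k)
}

# derived properties of the smoothing kernel, used by the segmenter to map
# smoothed-track noise back to raw per-bin noise
.kernelFactors <- function(sigma, trunc = 4) {
    k <- .gaussKernel(sigma, trunc)
    sk2 <- sum(k^2)
    rho1 <- sum(k[-1] * k[-length(k)]) / sk2
    list(sk2 = sk2, rho1 = rho1)
}

# masked kernel smoothing: weighted average over usable neighbours only
.kernelSmooth <- function(x, mask, kernel) {
    n <- length(x)
    h <- (length(kernel) - 1L) / 2L
    xm <- ifelse(mask, x, 0)
    num <- den <- numeric(n)
    for (off in -h:h) {
        w <- kernel[off + h + 1L]
        src <- seq_len(n) + off
        ok <- src >= 1L & src <= n
        num[ok] <- num[ok] + w * xm[src[ok]]
        den[ok] <- den[ok] + w * mask[src[ok]]
    }
    out <- rep(NA_real_, n)
    nz <- den > 0
    out[nz] <- num[nz] / den[nz]
    out
}

#' Kernel-smooth a TRE track
#'
#' Per-chromosome Gaussian kernel smoothing of the TRE values over usable
#' bins; unusable bins contribute neither to the kernel sums nor receive a
#' value. Smoothing greatly reduces the per-bin Poisson noise before
#' histogram construction and segmentation.
#'
#' @param profile a \code{\link{TREProfile}}.
#' @param bandwidthBins Gaussian kernel sd, in bins.
#' @param truncate kernel truncation, in multiples of the sd.
#' @return a smoothed \code{\link{TREProfile}}; \code{metadata()} records the
#'   bandwidth.
#' @export
smoothTRE <- function(profile, bandwidthBins = 3, truncate = 4) {
    stopifnot(is(profile, "TREProfile"), bandwidthBins >= 1)
    kernel <- .gaussKernel(bandwidthBins, truncate)
    tre <- profile$tre
    usable <- profile$usable
    sm <- rep(NA_real_, length(profile))
    for (chr in seqlevels(profile)) {
        idx <- which(as.character(seqnames(profile)) == chr)
        if (length(idx) == 0) next
        sm[idx] <- .kernelSmooth(ifelse(is.na(tre[idx]), 0, tre[idx]),
                                 usable[idx], kernel)
    }
    sm[!usable] <- NA_real_
    out <- granges(profile)
    mcols(out) <- DataFrame(tre = sm, usable = usable & is.finite(sm))
    out <- new("TREProfile", out)
    metadata(out) <- metadata(profile)
    metadata(out)$smoothed <- TRUE
    metadata(out)$bandwidthBins <- bandwidthBins
    metadata(out)$truncate <- truncate
    out
}
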