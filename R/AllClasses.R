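#' Genome layout: chromosomes and a fixed bin width
#'
#' A \code{GenomeLayout} records the chromosome names and lengths of the
#' (possibly scaled) genome under analysis together with the width of the
#' non-overlapping, half-open bins that tile each chromosome. All coverage
#' tracks, truth profiles and segment calls in the package are defined on a
#' layout.
#'
#' @slot seqinfo a \link[GenomeInfoDb]{Seqinfo} with chromosome lengths.
#' @slot binSize bin width in bp.
#'
#' @seealso \code{\link{genomeLayout}}, \code{\link{scaledGenomeLayout}},
#'   \code{\link{layoutBins}}
#' @export
setClass("GenomeLayout",
    representation(seqinfo = "Seqinfo", binSize = "integer"))

setValidity("GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    if (length(sl) == 0L) return("layout needs at least one chromosome")
    if (any(is.na(sl)) || any(sl <= 0)) return("chromosome lengths must be positive")
    if (length(object@binSize) != 1L || is.na(object@binSize) || object@binSize <= 0L)
        return("binSize must be a single positive integer")
    TRUE
})

#' Paired tumor/normal binned read counts
#'
#' A \code{GRanges} subclass whose ranges are the bins of a
#' \code{\link{GenomeLayout}} and whose metadata columns \code{tumor_count}
#' and \code{normal_count} hold the per-bin read counts of the tumor and the
#' matched normal sample.
#'
#' @export
setClass("BinnedCoverage", contains = "GRanges")

setValidity("BinnedCoverage", function(object) {
    mc <- mcols(object)
    need <- c("tumor_count", "normal_count")
    if (!all(need %in% colnames(mc)))
        return("mcols must contain tumor_count and normal_count")
    tc <- mc$tumor_count; nc <- mc$normal_count
    if (any(!is.finite(tc)) || any(!is.finite(nc)))
        return("counts must be finite")
    if (any(tc < 0) || any(nc < 0)) return("counts must be non-negative")
    TRUE
})

#' Tumor Read Enrichment track
#'
#' A \code{GRanges} subclass with one range per bin and metadata columns
#' \code{tre} (the double-normalized tumor/normal depth ratio; \code{NA} where
#' unusable) and \code{usable} (logical; bins with sufficient normal
#' coverage). Whether the track has been kernel-smoothed, and with which
#' bandwidth, is recorded in \code{metadata()}.
#'
#' @export
setClass("TREProfile", contains = "GRanges")

setValidity("TREProfile", function(object) {
    mc <- mcols(object)
    if (!all(c("tre", "usable") %in% colnames(mc)))
        return("mcols must contain tre and usable")
    if (any(mc$usable & !is.finite(mc$tre)))
        return("tre must be finite on usable bins")
    TRUE
})

#' Ground-truth copy-number profile of a simulated tumor
#'
#' A \code{GRanges} subclass listing the somatic copy-number alterations
#' (CNAs) of a simulated tumor genome, with metadata columns \code{tcn}
#' (total copy number, float; a population average in subclonal regions),
#' \code{macn} and \code{mcn} (major/minor allele copy number; population
#' averages where subclonal) and \code{clonal} (logical: all tumor cells
#' share the same integer state). Genome not covered by any range is
#' implicitly diploid (tcn 2, macn = mcn = 1, clonal). The layout and, for
#' subclone mixtures, the mixing fractions live in \code{metadata()}.
#'
#' @export
setClass("TruthProfile", contains = "GRanges")

setValidity("TruthProfile", function(object) {
    mc <- mcols(object)
    need <- c("tcn", "macn", "mcn", "clonal")
    if (!all(need %in% colnames(mc)))
        return("mcols must contain tcn, macn, mcn and clonal")
    if (any(mc$tcn < 0)) return("tcn must be >= 0")
    if (!isDisjoint(object)) return("truth segments must not overlap")
    cl <- mc$clonal & !is.na(mc$macn)
    if (any(cl & abs(mc$macn + mc$mcn - round(mc$tcn)) > 1e-8))
        return("macn + mcn must equal round(tcn) on clonal segments")
    if (any(cl & (mc$macn < mc$mcn | mc$mcn < 0)))
        return("macn >= mcn >= 0 violated")
    TRUE
})

#' Fitted lattice-tied Gaussian mixture model
#'
#' Holds the parameters of one converged EM fit of the copy-number lattice
#' model: the TRE of a segment with integer copy number c has expectation
#' \eqn{1 + \Delta (c - \pi)} where \eqn{\Delta = p / (p \pi + 2 (1 - p))},
#' p is the tumor purity and \eqn{\pi} the tumor ploidy.
#'
#' @slot purity tumor cell fraction, in (0, 1].
#' @slot ploidy length-weighted mean tumor copy number.
#' @slot delta lattice spacing of the TRE histogram, in TRE units.
#' @slot sigma per-bin TRE noise sd (segment means have sd
#'   \code{sigma/sqrt(n_bins)}).
#' @slot theta mixture weights over copy states \code{0:cMax}.
#' @slot logLik,bic,nParams model fit statistics; BIC uses the total number
#'   of usable bins as the sample size.
#' @slot converged logical; FALSE if EM hit the iteration cap.
#' @slot nBins,nSegments problem size of the fit.
#' @slot trace list of per-iteration diagnostics (log-likelihood path).
#'
#' @export
setClass("CopyNumberFit",
    representation(purity = "numeric", ploidy = "numeric", delta = "numeric",
        sigma = "numeric", theta = "numeric", logLik = "numeric",
        bic = "numeric", nParams = "integer", converged = "logical",
        nBins = "numeric", nSegments = "integer", trace = "list"))

setValidity("CopyNumberFit", function(object) {
    p <- object@purity; pi <- object@ploidy; d <- object@delta
    if (p <= 0 || p > 1) return("purity must be in (0, 1]")
    if (pi <= 0) return("ploidy must be positive")
    if (d <= 0) return("delta must be positive")
    if (abs(d - p / (p * pi + 2 * (1 - p))) > 1e-8)
        return("delta must satisfy delta = p/(p*ploidy + 2*(1-p))")
    th <- object@theta
    if (any(th < -1e-12) || abs(sum(th) - 1) > 1e-8)
        return("theta must be a probability vector")
    TRUE
})

#' Result of a full copy-number inference run
#'
#' Container returned by \code{\link{runInference}}: the selected model fit,
#' the per-segment copy-number calls (a \code{GRanges} with columns
#' \code{tcn_float}, \code{tcn_int}, \code{clonal}, \code{macn}, \code{mcn},
#' \code{mean_tre}, \code{n_bins}), the ranked period candidates that were
#' tried, and run diagnostics.
#'
#' @export
setClass("CopyNumberResult",
    representation(fit = "CopyNumberFit", calls = "GRanges",
        candidates = "data.frame", config = "list", diagnostics = "list"))

setMethod("show", "GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat("GenomeLayout:", length(sl), "chromosome(s),",
        sprintf("%.1f Mb total,", sum(as.numeric(sl)) / 1e6),
        object@binSize, "bp bins\n")
})

setMethod("show", "CopyNumberFit", function(object) {
    cat("CopyNumberFit\n")
    cat(sprintf("  purity  %.4f\n  ploidy  %.3f\n  delta   %.5f\n",
        object@purity, object@ploidy, object@delta))
    cat(sprintf("  sigma   %.4g   logLik %.2f   BIC %.2f\n",
        object@sigma, object@logLik, object@bic))
    cat(sprintf("  %d segments, %.0f bins, converged: %s\n",
        object@nSegments, object@nBins, object@converged))
})

setMethod("show", "CopyNumberResult", function(object) {
    cat("CopyNumberResult\n")
    show(object@fit)
    cl <- object@calls$clonal
    cat(sprintf("  calls: %d segments (%d clonal, %d subclonal), %d with MACN\n",
        length(object@calls), sum(cl), sum(!cl),
        sum(!is.na(object@calls$macn))))
})
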