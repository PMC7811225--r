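#' CallF: fraction of the genome assigned a copy number
#'
#' @param pred a \code{GRanges} of predicted segments (non-overlapping).
#' @param genomeLength total genome length in bp.
#' @return fraction in [0, 1].
#' @export
callF <- function(pred, genomeLength) {
    stopifnot(genomeLength > 0)
    if (!isDisjoint(pred))
        stop("predicted segments overlap; ill-formed prediction")
    sum(as.numeric(width(pred))) / genomeLength
}

#' FullC: length-weighted exponential concordance of two copy-number tracks
#'
#' Every overlap of a truth segment with a predicted segment is an
#' intersection (no minimum-overlap threshold); each contributes its length
#' times \eqn{e^{-|TC - PC|}} to the numerator and its length to the
#' denominator. Intersections where both tracks are normal are excluded
#' from both sums (copy number exactly 2 in TCN mode; major and minor
#' allele counts exactly 1 in MACN mode), so that calling everything diploid
#' scores nothing. In MACN mode only intersections where both tracks report
#' an allele-specific call enter the computation.
#'
#' @param truth,pred \code{GRanges} with the value column(s): \code{tcn} or
#'   \code{tcn_float} in TCN mode; \code{macn} and \code{mcn} in MACN mode.
#' @param mode "tcn" or "macn".
#' @return FullC in [0, 1]. Raises an error of class
#'   \code{noComparableRegions} when every intersection is excluded (the
#'   metric is undefined, not zero).
#' @examples
#' t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), tcn = 3)
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), tcn = 4)
#' fullC(t, p)  # exp(-1)
#' @export
fullC <- function(truth, pred, mode = c("tcn", "macn")) {
    mode <- match.arg(mode)
    valueCol <- function(gr) {
        if (mode == "tcn") {
            if ("tcn" %in% colnames(mcols(gr))) gr$tcn else gr$tcn_float
        } else gr$macn
    }
    tv <- valueCol(truth)
    pv <- valueCol(pred)
    hits <- findOverlaps(truth, pred, ignore.strand = TRUE)
    if (length(hits) == 0)
        stop(structure(class = c("noComparableRegions", "error", "condition"),
            list(message = "truth and prediction do not intersect",
                 call = sys.call())))
    qi <- queryHits(hits); si <- subjectHits(hits)
    ov <- pintersect(granges(truth)[qi], granges(pred)[si])
    w <- as.numeric(width(ov))
    tc <- tv[qi]; pc <- pv[si]
    if (mode == "tcn") {
        keep <- !is.na(tc) & !is.na(pc) & !(tc == 2 & pc == 2)
    } else {
        tm <- truth$mcn[qi]; pm <- pred$mcn[si]
        keep <- !is.na(tc) & !is.na(pc) &
            !(tc == 1 & pc == 1 & !is.na(tm) & !is.na(pm) &
                  tm == 1 & pm == 1)
    }
    if (!any(keep))
        stop(structure(class = c("noComparableRegions", "error", "condition"),
            list(message = paste("all intersections excluded (normal in",
                "both tracks or lacking calls); FullC undefined"),
                call = sys.call())))
    sum(w[keep] * exp(-abs(tc[keep] - pc[keep]))) / sum(w[keep])
}

#' Evaluate a call track against a truth profile
#'
#' Convenience wrapper computing CallF and FullC for total copy number and,
#' optionally, for the major-allele track restricted to segments where both
#' sides carry an allele-specific call.
#'
#' @param truth a \code{\link{TruthProfile}} (CNA segments; implicit diploid
#'   gaps are filled in before comparison).
#' @param calls a call \code{GRanges} from \code{\link{callTCN}} /
#'   \code{\link{assignMACN}}.
#' @param layout the \code{\link{GenomeLayout}} (for the genome length).
#' @param mode "tcn" or "macn".
#' @return list(callf, fullc, intersectedLength).
#' @export
evaluateCalls <- function(truth, calls, layout, mode = c("tcn", "macn")) {
    mode <- match.arg(mode)
    full <- fullTruthSegments(truth, layout)
    if (mode == "macn") {
        # truth MACN is defined on clonal segments only
        full <- full[full$clonal & !is.na(full$macn)]
        pred <- calls[!is.na(calls$macn)]
    } else {
        pred <- calls
    }
    cf <- callF(pred, genomeLength(layout))
    fc <- fullC(full, pred, mode)
    hits <- findOverlaps(full, pred, ignore.strand = TRUE)
    ov <- pintersect(granges(full)[queryHits(hits)],
                     granges(pred)[subjectHits(hits)])
    list(callf = cf, fullc = fc,
         intersectedLength = sum(as.numeric(width(ov))))
}
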