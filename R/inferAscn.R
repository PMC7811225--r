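#' Log ratios of allelic-coverage ratios (LAR) per segment
#'
#' For a heterozygous germline SNV with tumor allele counts (ta, tb) and
#' normal allele counts (na, nb), \deqn{LAR = \ln\frac{ta / tb}{na / nb}.}
#' SNVs with any of the four counts equal to zero are excluded (their LAR is
#' not finite) and tallied in \code{nExcludedZero} -- the model later
#' corrects component means for this truncation, which matters greatly at
#' low depth. SNVs with tumor or normal depth below \code{minDepth} are
#' excluded separately.
#'
#' @param snvs data.frame with columns chrom, pos, tumor_a, tumor_b,
#'   normal_a, normal_b.
#' @param segments a \code{GRanges} of (non-overlapping) segments.
#' @param minDepth minimum tumor and normal depth for a retained SNV.
#' @return list with one element per segment: list(lars, tumorDepths,
#'   normalDepths, nExcludedZero, nRetained).
#' @export
computeLAR <- function(snvs, segments, minDepth = 4L) {
    stopifnot(isDisjoint(segments))
    loci <- GRanges(snvs$chrom, IRanges(snvs$pos, snvs$pos))
    hit <- findOverlaps(loci, segments, select = "first")
    dt <- snvs$tumor_a + snvs$tumor_b
    dn <- snvs$normal_a + snvs$normal_b
    anyZero <- snvs$tumor_a == 0 | snvs$tumor_b == 0 |
        snvs$normal_a == 0 | snvs$normal_b == 0
    lowDepth <- !anyZero & (dt < minDepth | dn < minDepth)
    keep <- !anyZero & !lowDepth
    lar <- rep(NA_real_, nrow(snvs))
    lar[keep] <- log((snvs$tumor_a[keep] / snvs$tumor_b[keep]) /
                     (snvs$normal_a[keep] / snvs$normal_b[keep]))
    lapply(seq_along(segments), function(i) {
        inSeg <- which(!is.na(hit) & hit == i)
        ret <- inSeg[keep[inSeg]]
        list(lars = lar[ret],
             tumorDepths = dt[ret],
             normalDepths = dn[ret],
             allTumorDepths = dt[inSeg],
             allNormalDepths = dn[inSeg],
             allZero = anyZero[inSeg],
             nExcludedZero = sum(anyZero[inSeg]),
             nRetained = length(ret))
    })
}

#' Expected major-allele read fraction
#'
#' In a sample of purity p, a clonal segment with major/minor allele copy
#' numbers (M, m) yields tumor reads from the major allele with probability
#' \deqn{f = \frac{p M + (1 - p)}{p (M + m) + 2 (1 - p)}}
#' (normal cells contribute one copy of each allele).
#'
#' @param M,m major and minor allele copy number, M >= m >= 0.
#' @param p purity.
#' @return fraction in [0, 1].
#' @examples
#' expectedMajorFraction(2, 1, 0.5)  # 0.6
#' @export
expectedMajorFraction <- function(M, m, p) {
    stopifnot(M >= m, m >= 0)
    denom <- p * (M + m) + 2 * (1 - p)
    if (denom <= 0)
        stop("degenerate segment: zero expected allelic coverage")
    (p * M + (1 - p)) / denom
}

# E[ln(X / (n - X)) | 1 <= X <= n - 1], X ~ Binomial(n, f), exact enumeration
.truncatedLogitMean <- function(f, n) {
    x <- seq_len(n - 1)
    px <- dbinom(x, n, f)
    tot <- sum(px)
    if (tot <= 0) return(NaN)
    sum(px * log(x / (n - x))) / tot
}

# first two moments of the truncated logit at a given depth
.truncatedLogitMoments <- function(f, n) {
    x <- seq_len(n - 1)
    px <- dbinom(x, n, f)
    tot <- sum(px)
    if (tot <= 0) return(c(mean = NaN, var = NaN))
    lv <- log(x / (n - x))
    m1 <- sum(px * lv) / tot
    m2 <- sum(px * lv^2) / tot
    c(mean = m1, var = max(m2 - m1^2, 0))
}

#' Zero-exclusion-corrected expected LAR
#'
#' The naive expectation of a LAR component is the logit ln(f / (1 - f)),
#' but because SNVs with a zero allele count are excluded, the observable
#' tumor term is the expectation of ln(X / (n - X)) under a Binomial(n, f)
#' truncated to 1 <= X <= n - 1 -- at low depth this is pulled substantially
#' toward 0. The correction is computed by exact enumeration of binomial
#' outcomes, averaged over the supplied empirical depth distributions, with
#' the analogous truncated normal-sample term (f = 1/2; zero by symmetry)
#' subtracted.
#'
#' @param f expected major-allele fraction, strictly inside (0, 1);
#'   f of exactly 0 or 1 (complete LOH in a pure tumor) is signalled as an
#'   error of class \code{larSaturated} -- those candidates are scored
#'   through the exclusion mass instead (see \code{\link{fitMACN}}).
#' @param tumorDepths,normalDepths integer vectors of per-SNV depths
#'   (the empirical depth distribution of the segment).
#' @return expected LAR of the major-allele component.
#' @export
correctedLarMean <- function(f, tumorDepths, normalDepths) {
    if (f <= 0 || f >= 1)
        stop(structure(class = c("larSaturated", "error", "condition"),
            list(message = paste("major-allele fraction is 0 or 1;",
                "handle complete LOH through the exclusion-aware likelihood"),
                call = sys.call())))
    stopifnot(all(tumorDepths >= 2), all(normalDepths >= 2))
    tumorTab <- table(tumorDepths)
    tumorTerm <- sum(vapply(seq_along(tumorTab), function(i)
        tumorTab[[i]] * .truncatedLogitMean(f, as.integer(names(tumorTab)[i])),
        0.0)) / length(tumorDepths)
    normalTab <- table(normalDepths)
    normalTerm <- sum(vapply(seq_along(normalTab), function(i)
        normalTab[[i]] *
            .truncatedLogitMean(0.5, as.integer(names(normalTab)[i])),
        0.0)) / length(normalDepths)
    tumorTerm - normalTerm
}

# per-SNV probability of exclusion for a zero allele count on either the
# tumor side (X ~ Binomial(n_t, f)) or the normal side (Binomial(n_n, 1/2)),
# conditional on that SNV's observed depth pair; depth zero always excludes
.exclusionProb <- function(f, tumorDepths, normalDepths) {
    pKeepT <- 1 - dbinom(0, tumorDepths, f) -
        ifelse(tumorDepths > 0, dbinom(tumorDepths, tumorDepths, f), 0)
    pKeepN <- 1 - 2 * dbinom(0, normalDepths, 0.5) +
        ifelse(normalDepths == 0, 1, 0)
    pz <- 1 - pmax(pKeepT, 0) * pmax(pmin(pKeepN, 1), 0)
    pmin(pmax(pz, 1e-12), 1 - 1e-12)
}

#' Major/minor allele copy number of one clonal segment
#'
#' Scores every allele split (M, m) with M + m = tcn, M >= m: the retained
#' LARs are modelled as an equal-weight two-component Gaussian mixture at
#' +/- the corrected component mean (the sign is unidentifiable because the
#' germline allele labels are arbitrary). Component means and variances are
#' the exact truncated-binomial moments at each SNV's own tumor and normal
#' depth -- pooling SNVs of very different depths under one variance makes
#' the pooled LAR distribution heavy-tailed and systematically favours
#' imbalanced splits -- and a single variance scale factor is fit by maximum
#' likelihood per candidate to absorb residual overdispersion. The count of
#' zero-allele-coverage exclusions contributes a binomial exclusion-mass
#' term, which is what discriminates complete LOH (f = 1, all SNVs
#' excluded) in high-purity samples.
#'
#' @param segLars one element of \code{\link{computeLAR}} output.
#' @param tcn integer total copy number of the (clonal) segment.
#' @param p purity.
#' @param minSnvs minimum retained LARs (or zero-excluded SNVs) required.
#' @param sigmaFloor lower bound for the fitted component sd.
#' @return list(macn, mcn, score) -- macn/mcn are NA when the segment has
#'   too few informative SNVs.
#' @export
fitMACN <- function(segLars, tcn, p, minSnvs = 20L, sigmaFloor = 1e-3) {
    stopifnot(tcn == round(tcn), tcn >= 0)
    nInf <- segLars$nRetained + segLars$nExcludedZero
    if (nInf < minSnvs || (segLars$nRetained > 0 &&
                           length(segLars$tumorDepths) == 0))
        return(list(macn = NA_real_, mcn = NA_real_, score = NA_real_))
    if (tcn == 0)
        return(list(macn = 0, mcn = 0, score = 0))
    Ms <- seq.int(ceiling(tcn / 2), tcn)
    lars <- segLars$lars
    dts <- segLars$tumorDepths
    best <- NULL
    for (M in Ms) {
        m <- tcn - M
        f <- expectedMajorFraction(M, m, p)
        exclLL <- if (length(segLars$allTumorDepths)) {
            pz <- .exclusionProb(f, segLars$allTumorDepths,
                                 segLars$allNormalDepths)
            sum(log(pz[segLars$allZero])) + sum(log1p(-pz[!segLars$allZero]))
        } else 0
        if (f <= 1e-12 || f >= 1 - 1e-12) {
            ll <- exclLL + segLars$nRetained * log(1e-12)
        } else if (length(lars) == 0) {
            ll <- exclLL
        } else {
            ut <- sort(unique(dts))
            un <- sort(unique(segLars$normalDepths))
            momT <- vapply(ut, function(n) .truncatedLogitMoments(f, n),
                           c(mean = 0, var = 0))
            momN <- vapply(un, function(n) .truncatedLogitMoments(0.5, n),
                           c(mean = 0, var = 0))
            it <- match(dts, ut)
            inm <- match(segLars$normalDepths, un)
            mui <- momT["mean", it] - momN["mean", inm]
            sdi <- sqrt(pmax(momT["var", it] + momN["var", inm], 1e-3))
            mixLL <- function(logS) {
                s <- exp(logS)
                sum(log(0.5 * dnorm(lars, mui, s * sdi) +
                        0.5 * dnorm(lars, -mui, s * sdi) + 1e-300))
            }
            opt <- optimize(mixLL, log(c(max(sigmaFloor, 0.05), 10)),
                            maximum = TRUE)
            ll <- exclLL + opt$objective
        }
        if (is.null(best) || ll > best$score)
            best <- list(macn = M, mcn = m, score = ll)
    }
    best
}

#' Assign MACN/mcn to the clonal segments of a call track
#'
#' Runs \code{\link{fitMACN}} on every clonal segment with an integer TCN;
#' subclonal segments keep NA allele-specific calls (an averaged allele dose
#' across subclones has no single integer split). Emits a warning when the
#' tumor content (coverage x purity) is below 1X, where allele-specific
#' inference is underpowered.
#'
#' @param calls \code{GRanges} from \code{\link{callTCN}}.
#' @param snvs SNV count data.frame (see \code{\link{computeLAR}}).
#' @param p purity (from the selected model fit).
#' @param minDepth,minSnvs,sigmaFloor see \code{\link{computeLAR}} and
#'   \code{\link{fitMACN}}.
#' @param tumorContent optional coverage x purity, for the power warning.
#' @return \code{calls} with \code{macn}/\code{mcn} filled on clonal
#'   segments.
#' @export
assignMACN <- function(calls, snvs, p, minDepth = 4L, minSnvs = 20L,
                       sigmaFloor = 1e-3, tumorContent = NULL) {
    if (!is.null(tumorContent) && tumorContent < 1)
        warning("tumor content (coverage x purity) below 1X; ",
                "allele-specific copy number estimates will be unreliable")
    segLars <- computeLAR(snvs, calls, minDepth)
    for (i in which(calls$clonal & !is.na(calls$tcn_int))) {
        res <- fitMACN(segLars[[i]], calls$tcn_int[i], p, minSnvs,
                       sigmaFloor)
        calls$macn[i] <- res$macn
        calls$mcn[i] <- res$mcn
    }
    calls
}
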