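#' Histogram of smoothed TRE values
#'
#' The TRE histogram of a genome with copy-number alterations shows a comb of
#' peaks at the lattice positions \eqn{1 + \Delta (c - \pi)}; the spacing
#' \eqn{\Delta} is the quantity the period detector estimates. Values outside
#' \code{range} are clipped into the boundary bins and tallied.
#'
#' @param profile a (smoothed) \code{\link{TREProfile}}.
#' @param binWidth histogram bin width in TRE units.
#' @param range numeric length-2, histogram support.
#' @return an object of class \code{TreHistogram}: list with \code{centers},
#'   \code{counts}, \code{binWidth}, \code{nClipped}.
#' @export
treHistogram <- function(profile, binWidth = 0.005, range = c(0, 3)) {
    stopifnot(binWidth > 0, range[1] < range[2])
    x <- profile$tre[profile$usable]
    x <- x[is.finite(x)]
    if (length(x) == 0) stop("no usable TRE values to histogram")
    nClipped <- sum(x < range[1] | x > range[2])
    x <- pmin(pmax(x, range[1]), range[2])
    nb <- ceiling((range[2] - range[1]) / binWidth)
    idx <- pmin(floor((x - range[1]) / binWidth) + 1L, nb)
    counts <- tabulate(idx, nbins = nb)
    centers <- range[1] + (seq_len(nb) - 0.5) * binWidth
    structure(list(centers = centers, counts = counts, binWidth = binWidth,
                   nClipped = nClipped),
              class = "TreHistogram")
}

#' Autocorrelation of the TRE histogram
#'
#' Normalized autocorrelation of the mean-subtracted histogram counts;
#' a periodic comb of histogram peaks yields local ACF maxima at lags that
#' are multiples of the peak spacing.
#'
#' @param hist a \code{TreHistogram}.
#' @param maxLag maximum lag, in histogram bins (must be < number of bins).
#' @return data.frame with columns \code{lag} (bins) and \code{acf};
#'   \code{acf[lag == 0]} is 1.
#' @export
treAutocorrelation <- function(hist, maxLag = NULL) {
    counts <- as.numeric(hist$counts)
    if (is.null(maxLag)) maxLag <- length(counts) - 1L
    if (maxLag >= length(counts))
        stop("maxLag must be smaller than the number of histogram bins")
    if (var(counts) == 0)
        stop("histogram is constant; autocorrelation undefined")
    a <- acf(counts, lag.max = maxLag, plot = FALSE, demean = TRUE)
    data.frame(lag = 0:maxLag, acf = as.numeric(a$acf))
}

#' Period search bounds implied by purity and ploidy bounds
#'
#' The lattice relation \eqn{\Delta = p / (p \pi + 2 (1 - p))} is increasing
#' in purity p and decreasing in ploidy \eqn{\pi}, so box bounds on (p,
#' \eqn{\pi}) translate directly into bounds on the admissible period.
#'
#' @param purityBounds,ploidyBounds numeric length-2 vectors.
#' @return c(deltaMin, deltaMax).
#' @export
deltaBounds <- function(purityBounds = c(0.05, 1),
                        ploidyBounds = c(1.2, 6)) {
    lat <- function(p, pi) p / (p * pi + 2 * (1 - p))
    c(lat(purityBounds[1], ploidyBounds[2]),
      lat(purityBounds[2], ploidyBounds[1]))
}

#' Ranked period candidates from the histogram ACF
#'
#' Local maxima of the autocorrelation whose implied period lies within
#' \code{deltaRange} are ranked by ACF strength. A candidate whose lag is
#' within one histogram bin of an integer multiple (>= 2) of a stronger
#' candidate's lag is kept but down-ranked as a probable harmonic; the final
#' choice among candidates is delegated to the EM + BIC model fit.
#'
#' @param acfDf output of \code{\link{treAutocorrelation}}.
#' @param binWidth histogram bin width in TRE units.
#' @param deltaRange admissible period range (see \code{\link{deltaBounds}}).
#' @param topK maximum number of candidates returned.
#' @return data.frame with columns \code{delta}, \code{acfStrength},
#'   \code{lag}, \code{harmonic}, \code{rank}, strongest first.
#'   Raises an error of class \code{noPeriodicity} when no local maximum
#'   falls in range (typically a sample with little or no copy-number
#'   alteration).
#' @export
candidatePeriods <- function(acfDf, binWidth = 0.005,
                             deltaRange = deltaBounds(), topK = 5L) {
    stopifnot(deltaRange[1] > 0)
    r <- acfDf$acf
    lag <- acfDf$lag
    n <- length(r)
    isMax <- c(FALSE, r[2:(n - 1)] > r[1:(n - 2)] &
                   r[2:(n - 1)] >= r[3:n], FALSE)
    delta <- lag * binWidth
    sel <- which(isMax & lag > 0 & delta >= deltaRange[1] &
                     delta <= deltaRange[2])
    if (length(sel) == 0)
        stop(structure(class = c("noPeriodicity", "error", "condition"),
            list(message = paste("no periodicity detected in the TRE",
                "histogram; the sample may carry little or no copy-number",
                "alteration"), call = sys.call())))
    cand <- data.frame(delta = delta[sel], acfStrength = r[sel],
                       lag = lag[sel])
    cand <- cand[order(-cand$acfStrength), ]
    cand$harmonic <- FALSE
    if (nrow(cand) > 1) {
        for (i in 2:nrow(cand)) {
            stronger <- cand$lag[seq_len(i - 1)]
            mult <- cand$lag[i] / stronger
            cand$harmonic[i] <- any(mult >= 1.5 &
                abs(cand$lag[i] - round(mult) * stronger) <= 1)
        }
    }
    cand <- cand[order(cand$harmonic, -cand$acfStrength), ]
    cand <- head(cand, topK)
    cand$rank <- seq_len(nrow(cand))
    rownames(cand) <- NULL
    cand
}
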