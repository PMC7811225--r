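#' Pipeline configuration
#'
#' Collects every tunable of the inference pipeline with its default.
#' Defaults are validated against their documented ranges before any
#' computation.
#'
#' @param minNormalCount usable-bin threshold on normal counts.
#' @param bandwidthBins,truncate TRE smoothing kernel (sd in bins,
#'   truncation in sds).
#' @param histBinWidth,histRange TRE histogram resolution and support.
#' @param purityBounds,ploidyBounds admissible purity and ploidy, defining
#'   the period search range.
#' @param topK number of period candidates to refine.
#' @param segmentation a \code{\link{segmentationParams}}.
#' @param cMax largest copy state of the mixture.
#' @param clonalTol integer-distance threshold for the clonal call.
#' @param minDepth,minSnvs allele-specific inference thresholds.
#' @param em an \code{\link{emOptions}}.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(minNormalCount = 5L, bandwidthBins = 3,
                           truncate = 4, histBinWidth = 0.005,
                           histRange = c(0, 3),
                           purityBounds = c(0.05, 1),
                           ploidyBounds = c(1.2, 6), topK = 5L,
                           segmentation = segmentationParams(),
                           cMax = 8L, clonalTol = 0.2, minDepth = 4L,
                           minSnvs = 20L, em = emOptions()) {
    stopifnot(minNormalCount >= 0, bandwidthBins >= 1,
              histBinWidth > 0, histRange[1] < histRange[2],
              purityBounds[1] > 0, purityBounds[2] <= 1,
              ploidyBounds[1] > 0, diff(ploidyBounds) > 0,
              topK >= 1, cMax >= 2, clonalTol >= 0, clonalTol < 0.5,
              minDepth >= 2, minSnvs >= 1)
    structure(list(minNormalCount = minNormalCount,
                   bandwidthBins = bandwidthBins, truncate = truncate,
                   histBinWidth = histBinWidth, histRange = histRange,
                   purityBounds = purityBounds, ploidyBounds = ploidyBounds,
                   topK = as.integer(topK), segmentation = segmentation,
                   cMax = as.integer(cMax), clonalTol = clonalTol,
                   minDepth = as.integer(minDepth),
                   minSnvs = as.integer(minSnvs), em = em),
              class = "pipelineConfig")
}

#' Run the full copy-number inference pipeline
#'
#' Coverage to TRE, kernel smoothing, GADA-style segmentation, histogram
#' autocorrelation for period candidates, lattice-mixture EM per candidate,
#' BIC model selection, per-segment TCN calls and allele-specific calls on
#' clonal segments. Errors of class \code{noPeriodicity} or \code{noModel}
#' indicate a sample without a usable periodic TRE pattern (little or no
#' copy-number alteration).
#'
#' @param cov a \code{\link{BinnedCoverage}}.
#' @param snvs SNV allele-count data.frame (may be NULL to skip the
#'   allele-specific stage).
#' @param config a \code{\link{pipelineConfig}}.
#' @return a \code{\link{CopyNumberResult}}.
#' @examples
#' \donttest{
#' lay <- scaledGenomeLayout()
#' truth <- makeTruthProfile(lay, seed = 7)
#' sim <- simulatePair(truth, coverage = 5, purity = 0.5, seed = 7)
#' res <- runInference(sim$coverage, sim$snvs)
#' purity(res); ploidy(res)
#' }
#' @export
runInference <- function(cov, snvs = NULL, config = pipelineConfig()) {
    stopifnot(is(cov, "BinnedCoverage"), inherits(config, "pipelineConfig"))
    tre <- computeTRE(cov, config$minNormalCount)
    treSm <- smoothTRE(tre, config$bandwidthBins, config$truncate)
    segs <- segmentGenome(treSm, config$segmentation)
    # histogram the segment-denoised track: each usable bin carries its
    # segment's mean TRE, whose standard error is ~sqrt(n_bins) smaller than
    # the per-bin noise -- at 2X coverage the per-bin histogram peaks are
    # wider than the lattice spacing and carry no usable periodicity
    denoised <- treSm
    segHit <- findOverlaps(granges(treSm), segs, select = "first")
    ok <- denoised$usable & !is.na(segHit)
    denoised$tre[ok] <- segs$mean_tre[segHit[ok]]
    denoised$usable <- ok
    hist <- treHistogram(denoised, config$histBinWidth, config$histRange)
    dRange <- deltaBounds(config$purityBounds, config$ploidyBounds)
    maxLag <- min(ceiling(dRange[2] / config$histBinWidth) + 1L,
                  length(hist$counts) - 1L)
    acfDf <- treAutocorrelation(hist, maxLag)
    cand <- candidatePeriods(acfDf, config$histBinWidth, dRange,
                             config$topK)
    fits <- candidateFits(segs, cand, hist, config$cMax,
                          config$ploidyBounds, dRange, config$em)
    fit <- selectModel(fits)
    calls <- callTCN(fit, segs, config$clonalTol)
    if (!is.null(snvs)) {
        md <- metadata(cov)
        tc <- if (!is.null(md$coverage)) md$coverage * fit@purity else NULL
        calls <- assignMACN(calls, snvs, fit@purity, config$minDepth,
                            config$minSnvs, tumorContent = tc)
    }
    new("CopyNumberResult", fit = fit, calls = calls, candidates = cand,
        config = unclass(config),
        diagnostics = list(histogram = hist, acf = acfDf,
                           nFits = length(fits),
                           nUsableBins = sum(treSm$usable)))
}

#' Simulate-infer-evaluate benchmark over a purity/coverage grid
#'
#' For every (coverage, purity, seed) cell: generate a truth profile,
#' simulate the tumor/normal pair, run \code{\link{runInference}} and score
#' the calls with CallF/FullC for TCN and MACN. Failures (e.g. no detectable
#' periodicity) are recorded in the \code{status} column and the run
#' continues.
#'
#' @param purities,coverages,seeds grid to sweep.
#' @param layout genome layout to simulate on.
#' @param design a \code{\link{cnaDesign}}.
#' @param nSnvs SNV loci per sample.
#' @param twoSubclone simulate a 3:2 two-subclone mixture instead of a
#'   single clone.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame with one row per grid cell: coverage, purity, seed,
#'   purity_hat, ploidy_hat, tcn_fullc, tcn_callf, macn_fullc, macn_callf,
#'   status.
#' @export
runBenchmark <- function(purities, coverages, seeds = 1L,
                         layout = scaledGenomeLayout(),
                         design = cnaDesign(), nSnvs = 1e5L,
                         twoSubclone = FALSE,
                         config = pipelineConfig()) {
    grid <- expand.grid(coverage = coverages, purity = purities,
                        seed = seeds, KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        cv <- grid$coverage[i]; p <- grid$purity[i]; sd <- grid$seed[i]
        out <- data.frame(coverage = cv, purity = p, seed = sd,
                          purity_hat = NA_real_, ploidy_hat = NA_real_,
                          tcn_fullc = NA_real_, tcn_callf = NA_real_,
                          macn_fullc = NA_real_, macn_callf = NA_real_,
                          status = "ok", stringsAsFactors = FALSE)
        res <- tryCatch({
            truth <- if (twoSubclone)
                twoSubcloneTruth(layout, design, seed = sd)
            else makeTruthProfile(layout, design, seed = sd)
            sim <- simulatePair(truth, cv, p, nSnvs, seed = sd + 1000L)
            inf <- suppressWarnings(
                runInference(sim$coverage, sim$snvs, config))
            ev <- evaluateCalls(truth, segmentCalls(inf), layout, "tcn")
            out$purity_hat <- purity(inf)
            out$ploidy_hat <- ploidy(inf)
            out$tcn_fullc <- ev$fullc
            out$tcn_callf <- ev$callf
            evm <- tryCatch(
                evaluateCalls(truth, segmentCalls(inf), layout, "macn"),
                error = function(e) NULL)
            if (!is.null(evm)) {
                out$macn_fullc <- evm$fullc
                out$macn_callf <- evm$callf
            }
            out
        }, noPeriodicity = function(e) { out$status <- "NoPeriodicity"; out },
           noModel = function(e) { out$status <- "NoModel"; out },
           error = function(e) {
               out$status <- paste("error:", conditionMessage(e)); out })
        res
    })
    do.call(rbind, rows)
}
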