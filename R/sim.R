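#' CNA design parameters for the truth-profile generator
#'
#' The defaults reproduce the summary constraints of the simulated tumor
#' genome used throughout the package's benchmarks: 21 somatic copy-number
#' alterations with lengths spanning 5-135 Mb on a full (3 Gb) genome --
#' scaled proportionally on smaller layouts -- copy numbers 0-8 (2 excluded),
#' together covering about 28\% of the genome.
#'
#' @param nCna number of CNA segments.
#' @param lengthRangeFrac allowed segment length as a fraction of the genome
#'   (defaults to 5e6/3e9 .. 135e6/3e9).
#' @param affectedFraction target fraction of the genome covered by CNAs.
#' @param fractionTol acceptable deviation of the achieved fraction.
#' @param cnValues,cnWeights copy-number states sampled for CNA segments and
#'   their sampling weights; 2 (normal) is never a CNA state.
#' @param minGapBins minimum number of normal bins between adjacent CNAs.
#' @return a list of class \code{cnaDesign}.
#' @export
cnaDesign <- function(nCna = 21L,
                      lengthRangeFrac = c(5e6, 135e6) / 3e9,
                      affectedFraction = 0.28,
                      fractionTol = 0.01,
                      cnValues = c(0L, 1L, 3L, 4L, 5L, 6L, 7L, 8L),
                      cnWeights = c(1, 2, 2.5, 2, 1.5, 1, 0.8, 0.7),
                      minGapBins = 1L) {
    stopifnot(nCna >= 0, length(lengthRangeFrac) == 2,
              lengthRangeFrac[1] > 0, diff(lengthRangeFrac) >= 0,
              affectedFraction > 0, affectedFraction < 1,
              !2L %in% cnValues, length(cnValues) == length(cnWeights))
    structure(list(nCna = as.integer(nCna),
                   lengthRangeFrac = lengthRangeFrac,
                   affectedFraction = affectedFraction,
                   fractionTol = fractionTol,
                   cnValues = as.integer(cnValues), cnWeights = cnWeights,
                   minGapBins = as.integer(minGapBins)),
              class = "cnaDesign")
}

# draw nCna lengths in [lmin, lmax] summing (approximately) to target,
# by iterative clipped rescaling
.drawCnaLengths <- function(n, lmin, lmax, target) {
    l <- runif(n, lmin, lmax)
    for (i in 1:100) {
        l <- pmin(pmax(l * target / sum(l), lmin), lmax)
        if (abs(sum(l) - target) < 1e-6 * target) break
    }
    l
}

#' Generate a ground-truth CNA profile
#'
#' Draws a random set of non-overlapping CNA segments on the given layout
#' following a \code{\link{cnaDesign}}: segment lengths are drawn within the
#' (genome-scaled) allowed range and rescaled so the total affected fraction
#' hits the design target; total copy numbers are sampled from the design's
#' state set and each gets a consistent (macn, mcn) split with
#' macn >= mcn >= 0 and macn + mcn = tcn. Deterministic given \code{seed}.
#'
#' @param layout a \code{\link{GenomeLayout}}.
#' @param config a \code{\link{cnaDesign}}.
#' @param seed integer RNG seed.
#' @return a \code{\link{TruthProfile}} (CNA segments only; uncovered genome
#'   is implicitly diploid).
#' @examples
#' truth <- makeTruthProfile(scaledGenomeLayout(), seed = 1)
#' length(truth)                      # 21 alterations
#' sum(width(truth)) / genomeLength(scaledGenomeLayout())  # ~0.28
#' @export
makeTruthProfile <- function(layout, config = cnaDesign(), seed = 1L) {
    stopifnot(is(layout, "GenomeLayout"), inherits(config, "cnaDesign"))
    set.seed(seed)
    G <- genomeLength(layout)
    bs <- layout@binSize
    sl <- seqlengths(layout@seqinfo)
    if (config$nCna == 0L) {
        gr <- GRanges(seqinfo = layout@seqinfo)
        mcols(gr) <- DataFrame(tcn = numeric(0), macn = numeric(0),
                               mcn = numeric(0), clonal = logical(0))
        out <- new("TruthProfile", gr)
        metadata(out) <- list(layout = layout, config = config, seed = seed)
        return(out)
    }
    lmin <- config$lengthRangeFrac[1] * G
    lmax <- config$lengthRangeFrac[2] * G
    target <- config$affectedFraction * G
    if (config$nCna * lmin > target * (1 + config$fractionTol) ||
        config$nCna * lmax < target * (1 - config$fractionTol))
        stop("CNA design infeasible: nCna segments of the allowed length ",
             "range cannot cover the target fraction of the genome")
    len <- .drawCnaLengths(config$nCna, lmin, lmax, target)
    # snap to whole bins, preserving the total as far as possible
    lenBins <- pmax(round(len / bs), 1)
    if (abs(sum(lenBins) * bs / G - config$affectedFraction) >
        config$fractionTol)
        stop("CNA placement failure: affected fraction ",
             signif(sum(lenBins) * bs / G, 3), " outside target ",
             config$affectedFraction, " +/- ", config$fractionTol)
    nbinsChr <- ceiling(sl / bs)
    placedStart <- placedEnd <- placedChr <- rep(NA_real_, config$nCna)
    gap <- config$minGapBins * bs
    ord <- order(lenBins, decreasing = TRUE)  # place big segments first
    for (k in ord) {
        segLen <- lenBins[k] * bs
        ok <- FALSE
        for (try in 1:5000) {
            ci <- sample.int(length(sl), 1L, prob = as.numeric(sl))
            maxStartBin <- nbinsChr[ci] - lenBins[k]
            if (maxStartBin < 0) next
            s <- (sample.int(maxStartBin + 1L, 1L) - 1L) * bs + 1
            e <- min(s + segLen - 1, sl[ci])
            prev <- which(placedChr == ci)
            if (length(prev) == 0 ||
                all(e + gap < placedStart[prev] | s - gap > placedEnd[prev])) {
                placedChr[k] <- ci; placedStart[k] <- s; placedEnd[k] <- e
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("CNA placement failure: could not place a ",
                 signif(segLen / 1e6, 3),
                 " Mb segment without overlap after 5000 attempts")
    }
    tcn <- sample(config$cnValues, config$nCna, replace = TRUE,
                  prob = config$cnWeights)
    macn <- vapply(tcn, function(t)
        if (t == 0L) 0L else sample(seq.int(ceiling(t / 2), t), 1L), 1L)
    gr <- GRanges(names(sl)[placedChr], IRanges(placedStart, placedEnd),
                  seqinfo = layout@seqinfo)
    mcols(gr) <- DataFrame(tcn = as.numeric(tcn), macn = as.numeric(macn),
                           mcn = as.numeric(tcn - macn),
                           clonal = rep(TRUE, config$nCna))
    gr <- sort(gr)
    out <- new("TruthProfile", gr)
    metadata(out) <- list(layout = layout, config = config, seed = seed)
    out
}

#' Expand a truth profile to a full-genome segment track
#'
#' Inserts the implicit diploid (tcn 2, macn = mcn = 1) segments between the
#' CNAs so the returned track tiles the whole genome.
#'
#' @param truth a \code{\link{TruthProfile}}.
#' @param layout optional \code{\link{GenomeLayout}} supplying chromosome
#'   lengths when the profile's own seqinfo lacks them (e.g. after reading
#'   from TSV).
#' @return a \code{GRanges} tiling the genome with the same metadata columns.
#' @export
fullTruthSegments <- function(truth, layout = NULL) {
    if (is.null(layout)) layout <- metadata(truth)$layout
    si <- if (!is.null(layout)) layout@seqinfo else seqinfo(truth)
    sl <- seqlengths(si)
    if (any(is.na(sl)))
        stop("chromosome lengths unavailable; supply a GenomeLayout")
    truth <- GRanges(seqnames(truth), ranges(truth), seqinfo = si,
                     tcn = truth$tcn, macn = truth$macn, mcn = truth$mcn,
                     clonal = truth$clonal)
    genome <- GRanges(names(sl), IRanges(1, sl), seqinfo = si)
    normal <- GenomicRanges::setdiff(genome, granges(truth))
    if (length(normal)) {
        mcols(normal) <- DataFrame(tcn = 2, macn = 1, mcn = 1, clonal = TRUE)
    } else {
        mcols(normal) <- DataFrame(tcn = numeric(0), macn = numeric(0),
                                   mcn = numeric(0), clonal = logical(0))
    }
    sort(c(granges(truth, use.mcols = TRUE), normal))
}

#' Mix subclone truth profiles into a population-average profile
#'
#' Averages the copy-number tracks of several subclones weighted by their
#' fractions within the tumor-cell population. Regions where all subclones
#' agree on (tcn, macn, mcn) stay clonal; elsewhere the averaged values are
#' recorded and the region is flagged subclonal.
#'
#' @param truths list of \code{\link{TruthProfile}}s on one layout.
#' @param fractions subclone proportions, summing to 1.
#' @return a \code{\link{TruthProfile}}; \code{metadata()$subcloneFractions}
#'   records the mix.
#' @examples
#' lay <- genomeLayout(c(chr1 = 1e6), 1000)
#' t1 <- makeTruthProfile(lay, cnaDesign(nCna = 0), seed = 1)
#' mixSubclones(list(t1, t1), c(0.5, 0.5))  # identity
#' @export
mixSubclones <- function(truths, fractions) {
    stopifnot(length(truths) >= 1, length(fractions) == length(truths))
    if (abs(sum(fractions) - 1) > 1e-8)
        stop("subclone fractions must sum to 1")
    sl <- seqlengths(seqinfo(truths[[1]]))
    for (t in truths[-1])
        if (!identical(seqlengths(seqinfo(t)), sl))
            stop("subclone truth profiles are on different genome layouts")
    tracks <- lapply(truths, fullTruthSegments)
    pieces <- GenomicRanges::disjoin(do.call(c, lapply(tracks, granges)))
    vals <- lapply(tracks, function(tr) {
        hit <- findOverlaps(pieces, tr, select = "first")
        as.data.frame(mcols(tr)[hit, ])
    })
    tcn <- Reduce(`+`, Map(function(v, f) f * v$tcn, vals, fractions))
    macn <- Reduce(`+`, Map(function(v, f) f * v$macn, vals, fractions))
    agree <- Reduce(`&`, lapply(vals, function(v)
        v$clonal & v$tcn == vals[[1]]$tcn & v$macn == vals[[1]]$macn))
    mcols(pieces) <- DataFrame(tcn = tcn, macn = macn, mcn = tcn - macn,
                               clonal = agree)
    # drop fully-normal clonal pieces; merge adjacent identical states
    keep <- !(pieces$clonal & pieces$tcn == 2 & pieces$macn == 1)
    pieces <- pieces[keep]
    if (length(pieces) > 1) {
        same <- c(FALSE, tail(pieces$tcn, -1) == head(pieces$tcn, -1) &
                      tail(pieces$macn, -1) == head(pieces$macn, -1) &
                      tail(pieces$clonal, -1) == head(pieces$clonal, -1) &
                      tail(start(pieces), -1) == head(end(pieces), -1) + 1 &
                      as.character(tail(seqnames(pieces), -1)) ==
                          as.character(head(seqnames(pieces), -1)))
        grp <- cumsum(!same)
        merged <- unlist(range(S4Vectors::split(pieces, grp)))
        mcols(merged) <- mcols(pieces)[!duplicated(grp), ]
        pieces <- merged
    }
    out <- new("TruthProfile", sort(pieces))
    md <- metadata(truths[[1]])
    md$subcloneFractions <- fractions
    metadata(out) <- md
    out
}

#' Design a two-subclone tumor truth
#'
#' Builds two subclone profiles that share most CNAs but differ in
#' \code{nDiffer} regions, then mixes them at the given fractions
#' (default 3:2, i.e. 0.6/0.4). One differing region is designed so that its
#' population-average total copy number is exactly an integer
#' (tcn 2 in subclone one, 7 in subclone two, average 0.6*2 + 0.4*7 = 4):
#' a subclonal region that a caller will legitimately report as clonal.
#'
#' @param layout a \code{\link{GenomeLayout}}.
#' @param config a \code{\link{cnaDesign}} for the shared backbone.
#' @param fractions two subclone proportions summing to 1.
#' @param nDiffer number of regions in which the subclones differ.
#' @param seed integer RNG seed.
#' @return a mixed \code{\link{TruthProfile}};
#'   \code{metadata()$designedRegion} marks the integer-average region.
#' @export
twoSubcloneTruth <- function(layout, config = cnaDesign(),
                             fractions = c(0.6, 0.4), nDiffer = 6L,
                             seed = 1L) {
    stopifnot(length(fractions) == 2, nDiffer >= 1)
    base <- makeTruthProfile(layout, config, seed = seed)
    set.seed(seed + 101L)
    clone2 <- granges(base, use.mcols = TRUE)
    nMod <- min(nDiffer - 1L, length(base))
    mod <- sample(length(base), nMod)
    for (i in mod) {
        old <- clone2$tcn[i]
        pick <- setdiff(config$cnValues, old)
        t2 <- sample(pick, 1L,
                     prob = config$cnWeights[match(pick, config$cnValues)])
        clone2$tcn[i] <- t2
        clone2$macn[i] <- if (t2 == 0) 0 else
            sample(seq.int(ceiling(t2 / 2), t2), 1L)
        clone2$mcn[i] <- t2 - clone2$macn[i]
    }
    # designed region: diploid in clone 1, copy 7 in clone 2
    bs <- layout@binSize
    lenBp <- round(mean(config$lengthRangeFrac) * genomeLength(layout) /
                   bs) * bs
    gapTrack <- fullTruthSegments(base)
    gapTrack <- gapTrack[gapTrack$tcn == 2 & width(gapTrack) >= lenBp + 2 * bs]
    if (length(gapTrack) == 0)
        stop("no diploid gap large enough for the designed subclonal region")
    g <- gapTrack[which.max(width(gapTrack))]
    s <- start(g) + bs * floor((width(g) - lenBp) / (2 * bs))
    designed <- GRanges(seqnames(g), IRanges(s, s + lenBp - 1),
                        seqinfo = seqinfo(base))
    mcols(designed) <- DataFrame(tcn = 7, macn = 4, mcn = 3, clonal = TRUE)
    clone2 <- new("TruthProfile", sort(c(granges(clone2, use.mcols = TRUE),
                                         designed)))
    metadata(clone2) <- metadata(base)
    mixed <- mixSubclones(list(base, clone2), fractions)
    metadata(mixed)$designedRegion <- granges(designed)
    mixed
}

#' Simulate a binned tumor/normal pair with SNV allele counts
#'
#' Count-level emulation of proportional tumor/normal mixing: normal bin
#' counts are Poisson with genome-mean depth \code{coverage}; tumor bin
#' counts are Poisson with the normal rate scaled by
#' \eqn{(p \cdot tcn + 2 (1 - p)) / 2} for sample purity p. Heterozygous SNV
#' loci are placed uniformly; normal allele counts are Binomial(depth, 0.5)
#' and tumor allele counts Binomial(depth, f) with
#' \eqn{f = (p \cdot macn + (1 - p)) / (p \cdot tcn + 2 (1 - p))}, the major
#' allele assigned to a random germline allele per locus. Deterministic given
#' \code{seed}.
#'
#' @param truth a \code{\link{TruthProfile}} carrying its layout in
#'   \code{metadata()}.
#' @param coverage mean sequencing depth (e.g. 2, 5, 10).
#' @param purity tumor-cell fraction in [0, 1].
#' @param nSnvs number of heterozygous germline SNV loci.
#' @param seed integer RNG seed.
#' @param readLength read length in bp used to convert depth to read counts.
#' @return list with elements \code{coverage} (a
#'   \code{\link{BinnedCoverage}}) and \code{snvs} (a data.frame with columns
#'   chrom, pos, tumor_a, tumor_b, normal_a, normal_b; loci with zero normal
#'   depth are dropped).
#' @export
simulatePair <- function(truth, coverage, purity, nSnvs = 1e5L, seed = 1L,
                         readLength = 100) {
    stopifnot(is(truth, "TruthProfile"), coverage > 0)
    if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
    layout <- metadata(truth)$layout
    if (is.null(layout)) stop("truth profile carries no layout metadata")
    set.seed(seed)
    p <- purity
    bins <- layoutBins(layout)
    hit <- findOverlaps(bins, truth, select = "first")
    tcnBin <- ifelse(is.na(hit), 2, truth$tcn[hit])
    if (any(!is.finite(tcnBin))) stop("tcn undefined at some bins")
    lam <- coverage * width(bins) / readLength
    normalCount <- rpois(length(bins), lam)
    tumorCount <- rpois(length(bins), lam * (p * tcnBin + 2 * (1 - p)) / 2)
    cov <- bins
    mcols(cov) <- DataFrame(tumor_count = tumorCount,
                            normal_count = normalCount)
    cov <- new("BinnedCoverage", cov)
    metadata(cov) <- list(layout = layout, coverage = coverage,
                          purity = purity, readLength = readLength)

    sl <- seqlengths(layout@seqinfo)
    ci <- sample.int(length(sl), nSnvs, replace = TRUE, prob = as.numeric(sl))
    pos <- floor(runif(nSnvs) * sl[ci]) + 1
    o <- order(ci, pos)
    ci <- ci[o]; pos <- pos[o]
    loci <- GRanges(names(sl)[ci], IRanges(pos, pos),
                    seqinfo = layout@seqinfo)
    hit <- findOverlaps(loci, truth, select = "first")
    t <- ifelse(is.na(hit), 2, truth$tcn[hit])
    M <- ifelse(is.na(hit), 1, truth$macn[hit])
    denom <- p * t + 2 * (1 - p)
    f <- ifelse(denom > 0, (p * M + (1 - p)) / denom, 0.5)
    dn <- rpois(nSnvs, coverage)
    dt <- rpois(nSnvs, coverage * denom / 2)
    swap <- runif(nSnvs) < 0.5
    fl <- ifelse(swap, 1 - f, f)
    ta <- rbinom(nSnvs, dt, fl)
    na <- rbinom(nSnvs, dn, 0.5)
    keep <- dn > 0
    snvs <- data.frame(chrom = names(sl)[ci], pos = pos,
                       tumor_a = ta, tumor_b = dt - ta,
                       normal_a = na, normal_b = dn - na)[keep, ]
    rownames(snvs) <- NULL
    list(coverage = cov, snvs = snvs)
}
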