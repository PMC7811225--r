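#' Construct a genome layout
#'
#' @param seqlengths named numeric vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 1000).
#' @return a \code{\link{GenomeLayout}}.
#' @examples
#' genomeLayout(c(chr1 = 2e6, chr2 = 1e6), binSize = 1000)
#' @export
genomeLayout <- function(seqlengths, binSize = 1000L) {
    if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
        stop("seqlengths must be named by chromosome")
    new("GenomeLayout",
        seqinfo = Seqinfo(names(seqlengths), as.integer(seqlengths)),
        binSize = as.integer(binSize))
}

#' Preset layouts
#'
#' \code{scaledGenomeLayout} is a 300 Mb desk-scale genome (three chromosomes
#' of 120, 100 and 80 Mb) on which the default CNA design keeps the full
#' genome's 21-alteration count and 28\% affected fraction with segment
#' lengths scaled proportionally (one tenth of the full-genome 5-135 Mb
#' range). \code{fullGenomeLayout} is the GRCh37 autosome complement.
#'
#' @param binSize bin width in bp.
#' @return a \code{\link{GenomeLayout}}.
#' @export
scaledGenomeLayout <- function(binSize = 1000L) {
    genomeLayout(c(chr1 = 120e6, chr2 = 100e6, chr3 = 80e6), binSize)
}

#' @rdname scaledGenomeLayout
#' @export
fullGenomeLayout <- function(binSize = 1000L) {
    # GRCh37 autosome lengths
    sl <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
            159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
            115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
            59128983, 63025520, 48129895, 51304566)
    names(sl) <- paste0("chr", 1:22)
    genomeLayout(sl, binSize)
}

#' Bins of a layout
#'
#' Tiles every chromosome of a layout with non-overlapping, half-open bins of
#' the layout's bin size (the last bin of a chromosome may be shorter).
#'
#' @param layout a \code{\link{GenomeLayout}}.
#' @return a \code{GRanges}, one range per bin, in genome order.
#' @export
layoutBins <- function(layout) {
    stopifnot(is(layout, "GenomeLayout"))
    bins <- tileGenome(layout@seqinfo, tilewidth = layout@binSize,
                       cut.last.tile.in.chrom = TRUE)
    sort(bins)
}

#' Total genome length of a layout in bp
#' @param layout a \code{\link{GenomeLayout}}.
#' @return numeric scalar.
#' @export
genomeLength <- function(layout) {
    sum(as.numeric(seqlengths(layout@seqinfo)))
}

#' @rdname genomeLayout
#' @param x a \code{GenomeLayout}.
#' @export
binSize <- function(x) x@binSize
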