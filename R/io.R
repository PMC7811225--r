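#' Read and write the package's TSV formats
#'
#' All interval formats use 0-based half-open coordinates on disk (BED
#' convention) and 1-based closed \code{GRanges} in memory. Binned coverage:
#' chrom, start, end, tumor_count, normal_count. SNV counts: chrom, pos
#' (1-based), tumor_a, tumor_b, normal_a, normal_b. Truth/segment profiles:
#' chrom, start, end plus the value columns of the track.
#'
#' @param x object to write.
#' @param file path.
#' @name periodic-cn-io
NULL

.grToBed <- function(gr, extraCols) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    cbind(df, as.data.frame(mcols(gr))[, extraCols, drop = FALSE])
}

.writeTsv <- function(df, file) {
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname periodic-cn-io
#' @export
writeBinnedCoverage <- function(x, file) {
    stopifnot(is(x, "BinnedCoverage"))
    .writeTsv(.grToBed(x, c("tumor_count", "normal_count")), file)
}

#' @rdname periodic-cn-io
#' @param layout a \code{\link{GenomeLayout}}; inferred from the file
#'   (chromosome spans and modal bin width) when NULL.
#' @export
readBinnedCoverage <- function(file, layout = NULL) {
    df <- read.delim(file)
    need <- c("chrom", "start", "end", "tumor_count", "normal_count")
    if (!all(need %in% names(df)))
        stop("malformed binned-coverage TSV: expected columns ",
             paste(need, collapse = ", "))
    if (is.null(layout)) {
        sl <- tapply(df$end, df$chrom, max)
        layout <- genomeLayout(setNames(as.numeric(sl), names(sl)),
                               binSize = median(df$end - df$start))
    }
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  seqinfo = layout@seqinfo)
    mcols(gr) <- DataFrame(tumor_count = df$tumor_count,
                           normal_count = df$normal_count)
    out <- new("BinnedCoverage", sort(gr))
    metadata(out) <- list(layout = layout)
    out
}

#' @rdname periodic-cn-io
#' @export
writeSnvCounts <- function(x, file) .writeTsv(x, file)

#' @rdname periodic-cn-io
#' @export
readSnvCounts <- function(file) {
    df <- read.delim(file)
    need <- c("chrom", "pos", "tumor_a", "tumor_b", "normal_a", "normal_b")
    if (!all(need %in% names(df)))
        stop("malformed SNV-count TSV: expected columns ",
             paste(need, collapse = ", "))
    df
}

#' @rdname periodic-cn-io
#' @export
writeTruthProfile <- function(x, file) {
    stopifnot(is(x, "TruthProfile"))
    df <- .grToBed(x, c("tcn", "macn", "mcn"))
    df$clonal_flag <- as.integer(x$clonal)
    .writeTsv(df, file)
}

#' @rdname periodic-cn-io
#' @export
readTruthProfile <- function(file, layout = NULL) {
    df <- read.delim(file)
    si <- if (!is.null(layout)) layout@seqinfo else NULL
    gr <- if (is.null(si)) GRanges(df$chrom, IRanges(df$start + 1L, df$end))
          else GRanges(df$chrom, IRanges(df$start + 1L, df$end), seqinfo = si)
    mcols(gr) <- DataFrame(tcn = df$tcn, macn = df$macn, mcn = df$mcn,
                           clonal = as.logical(df$clonal_flag))
    out <- new("TruthProfile", sort(gr))
    if (!is.null(layout)) metadata(out)$layout <- layout
    out
}

#' @rdname periodic-cn-io
#' @export
writeTREProfile <- function(x, file) {
    stopifnot(is(x, "TREProfile"))
    .writeTsv(.grToBed(x, c("tre", "usable")), file)
}

#' @rdname periodic-cn-io
#' @export
writeSegmentCalls <- function(x, file) {
    .writeTsv(.grToBed(x, c("tcn_float", "tcn_int", "clonal", "macn",
                            "mcn")), file)
}

#' @rdname periodic-cn-io
#' @export
readSegmentCalls <- function(file) {
    df <- read.delim(file)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr) <- DataFrame(df[, setdiff(names(df),
                                        c("chrom", "start", "end"))])
    sort(gr)
}

#' @rdname periodic-cn-io
#' @param result a \code{\link{CopyNumberResult}}.
#' @param seed seed recorded in the summary.
#' @export
writeSummaryJSON <- function(result, file, seed = NA) {
    fit <- result@fit
    summary <- list(
        purity = fit@purity, ploidy = fit@ploidy, delta = fit@delta,
        sigma = fit@sigma, logLik = fit@logLik, bic = fit@bic,
        n_segments = fit@nSegments, n_bins = fit@nBins,
        converged = fit@converged,
        version = as.character(utils::packageVersion("PeriodicCN")),
        seed = seed)
    write_json(summary, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
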