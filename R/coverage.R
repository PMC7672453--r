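#' RPKM-normalized binned coverage
#'
#' Counts fragment overlaps in fixed-width bins tiling the genome (default
#' 10 bp) and normalizes to reads per kilobase per million mapped fragments:
#' `RPKM = count / (binWidth/1000) / (total/1e6)`. Single-end reads are
#' extended to `fragmentLength` first. The conservation identity
#' `sum(RPKM * bin_kb * total/1e6) == total overlap count` holds exactly.
#'
#' @param reads one library's read `GRanges`.
#' @param genome `Seqinfo`.
#' @param binWidth bin width in bp (default 10).
#' @param fragmentLength extension length for single-end reads.
#' @param label library label carried in `mcols()$label`.
#' @return `GRanges` of bins with metadata columns `score` (RPKM) and
#'   `label`. Use [writeBedGraph()] to export (typically with
#'   `merge = TRUE` to run-length collapse zero stretches).
#' @export
coverageRpkm <- function(reads, genome, binWidth = 10,
                         fragmentLength = 147, label = "library") {
    if (binWidth <= 0) stop("binWidth must be positive")
    frags <- .toFragments(reads, fragmentLength)
    total <- length(frags)
    if (total == 0L) stop("library has zero fragments")
    bins <- tileGenome(seqlengths(genome), tilewidth = as.integer(binWidth),
                       cut.last.tile.in.chrom = TRUE)
    cts <- countOverlaps(bins, frags, ignore.strand = TRUE)
    mcols(bins)$score <- cts / (binWidth / 1000) / (total / 1e6)
    mcols(bins)$label <- label
    bins
}
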