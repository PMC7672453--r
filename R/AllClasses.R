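#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Windows-by-libraries count container
#'
#' A `WindowCounts` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' whose rows are genome-grid windows (or any genomic intervals) and whose
#' columns are sequencing libraries. The `"counts"` assay holds non-negative
#' integer fragment-overlap counts; `colData()$totals` stores the total number
#' of counted fragments per library (the library size used for CPM and GLM
#' offsets); `rowData()$abundance` stores the per-window mean log2-CPM
#' (prior count 0.5).
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    }
    if (!"totals" %in% colnames(colData(object)))
        msg <- c(msg, "colData()$totals is required")
    else {
        tot <- colData(object)$totals
        if (any(tot < 0)) msg <- c(msg, "library totals must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a WindowCounts object
#'
#' @param windows `GRanges` of windows, one per row of `counts`.
#' @param counts integer matrix, windows x libraries.
#' @param totals numeric vector of per-library total counted fragments;
#'   defaults to the column sums.
#' @param priorCount prior added to counts before the log2-CPM abundance
#'   computation (guards zero counts).
#' @return A [WindowCounts-class] object with `rowData()$abundance` filled in.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 151), width = 150))
#' wc <- WindowCounts(gr, matrix(c(5L, 0L, 3L, 2L), 2), totals = c(100, 120))
#' abundance(wc)
#' @export
WindowCounts <- function(windows, counts, totals = colSums(counts),
                         priorCount = 0.5) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (length(windows) != nrow(counts))
        stop("length(windows) must equal nrow(counts)")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
    cd <- DataFrame(totals = as.numeric(totals), row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = windows, colData = cd)
    wc <- new("WindowCounts", se)
    SummarizedExperiment::rowData(wc)$abundance <-
        .meanLog2Cpm(counts, as.numeric(totals), priorCount)
    wc
}

## mean over libraries of log2((count + prior) / (total + 2*prior) * 1e6)
.meanLog2Cpm <- function(counts, totals, priorCount = 0.5) {
    if (nrow(counts) == 0L) return(numeric(0))
    l <- .log2Cpm(counts, totals, priorCount)
    rowMeans(l)
}

.log2Cpm <- function(counts, totals, priorCount = 0.5) {
    sweep(log2(counts + priorCount), 2,
          log2(totals + 2 * priorCount) - log2(1e6), "-")
}

#' Global background enrichment model
#'
#' Summarizes non-specific coverage by counting fragments in wide contiguous
#' bins (default 2 kb), converting to log2-CPM and rescaling to the working
#' window width so bin and window abundances live on the same scale. The
#' median rescaled bin abundance is the global background level that window
#' filtering subtracts.
#'
#' @slot binWidth width in bp of the background bins.
#' @slot windowWidth window width in bp the abundances are rescaled to.
#' @slot binAbundance numeric, per-bin rescaled log2-CPM.
#' @slot globalBackground median of `binAbundance`.
#' @export
setClass("BackgroundModel", representation(
    binWidth = "numeric",
    windowWidth = "numeric",
    binAbundance = "numeric",
    globalBackground = "numeric"
))

setValidity("BackgroundModel", function(object) {
    if (object@binWidth < object@windowWidth)
        return("binWidth must be >= windowWidth")
    TRUE
})

#' Synthetic-experiment configuration
#'
#' Holds every knob of the synthetic ChIP-seq generator: genome, promoter
#' architecture, the two-component log-normal abundance mixture, condition /
#' replicate layout, planted differential sets and effect sizes, per-library
#' immunoprecipitation-bias amplitudes, negative-binomial dispersion,
#' background rate, and the seed. With a fixed seed the generator is
#' deterministic. Construct with [simConfig()].
#'
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    genome = "ANY",              # Seqinfo
    nPromoters = "integer",
    fracK4 = "numeric",
    fracK27 = "numeric",
    fracBivalent = "numeric",
    meanlogLow = "numeric",
    sdlogLow = "numeric",
    meanlogHigh = "numeric",
    sdlogHigh = "numeric",
    conditions = "character",
    replicates = "integer",
    nDifferential = "integer",
    nDifferentialNonTG = "integer",
    lfcRange = "numeric",
    fracGain = "numeric",
    overlapNonTG = "numeric",
    bivalentDiffWeight = "numeric",
    dispersion = "numeric",
    backgroundRate = "numeric",
    libSizeFactorRange = "numeric",
    biasAmplitude = "numeric",
    outlierReplicate = "logical",
    fragmentLength = "integer",
    readLength = "integer",
    mapqFailRate = "numeric"
))

#' Planted ground truth of a synthetic experiment
#'
#' @slot promoters `GRanges` of promoter TSS positions with per-promoter
#'   truth columns (enrichment flags, mixture component, base abundances,
#'   true log2 fold changes).
#' @slot libraries `DataFrame` with one row per library (condition,
#'   replicate, bias amplitude, library-size factor, outlier flag).
#' @slot seed integer seed the experiment was generated from.
#' @export
setClass("SimTruth", representation(
    promoters = "GRanges",
    libraries = "DataFrame",
    seed = "integer"
))

setMethod("show", "WindowCounts", function(object) {
    cat("WindowCounts with", nrow(object), "windows and",
        ncol(object), "libraries\n")
    callNextMethod()
})

setMethod("show", "BackgroundModel", function(object) {
    cat("BackgroundModel:", length(object@binAbundance), "bins of",
        object@binWidth, "bp (rescaled to", object@windowWidth, "bp)\n")
    cat("  global background (log2-CPM):",
        format(object@globalBackground, digits = 4), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nPromoters, "promoters,",
        length(object@conditions), "conditions x", object@replicates,
        "replicates, seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", length(object@promoters), "promoters,",
        nrow(object@libraries), "libraries, seed", object@seed, "\n")
})
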