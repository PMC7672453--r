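#' @importFrom BiocGenerics counts
NULL

#' Accessors for WindowCounts and friends
#'
#' `counts()` returns the windows x libraries integer matrix, `libSizes()`
#' the per-library totals, `abundance()` the per-window mean log2-CPM, and
#' `windowRanges()` the window coordinates. `globalBackground()` extracts the
#' scalar background level from a [BackgroundModel-class].
#'
#' @param object a `WindowCounts` or `BackgroundModel`.
#' @return See details; plain vectors/matrices or a `GRanges`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "WindowCounts", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))

#' @rdname accessors
#' @export
setMethod("libSizes", "WindowCounts", function(object)
    stats::setNames(colData(object)$totals, colnames(object)))

#' @rdname accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))

#' @rdname accessors
#' @export
setMethod("abundance", "WindowCounts", function(object)
    SummarizedExperiment::rowData(object)$abundance)

#' @rdname accessors
#' @export
setGeneric("windowRanges", function(object) standardGeneric("windowRanges"))

#' @rdname accessors
#' @export
setMethod("windowRanges", "WindowCounts", function(object)
    SummarizedExperiment::rowRanges(object))

#' @rdname accessors
#' @export
setGeneric("globalBackground",
           function(object, ...) standardGeneric("globalBackground"))

#' @rdname accessors
#' @export
setMethod("globalBackground", "BackgroundModel",
          function(object, ...) object@globalBackground)

#' @rdname accessors
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @rdname accessors
#' @export
setMethod("simTruth", "SimTruth", function(object)
    list(promoters = object@promoters, libraries = object@libraries,
         seed = object@seed))
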