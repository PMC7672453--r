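#' @importFrom stats loess predict median cmdscale setNames
NULL

#' MA values of one library against the geometric-mean reference
#'
#' The reference is the geometric-mean pseudo-library over all samples
#' (equivalently, the per-window mean of prior-count-guarded log2-CPM
#' values). For library `j`, `M = log2CPM_j - reference` and `A` is the
#' reference itself (the average abundance).
#'
#' @param wc [WindowCounts-class], usually restricted to filtered windows.
#' @param library column index or name.
#' @param priorCount prior count guarding zeros (default 0.5).
#' @return `data.frame` with columns `M` and `A`.
#' @export
maValues <- function(wc, library, priorCount = 0.5) {
    l <- .log2Cpm(counts(wc), libSizes(wc), priorCount)
    ref <- rowMeans(l)
    data.frame(M = l[, library] - ref, A = ref)
}

#' Loess normalization offsets for abundance-dependent biases
#'
#' Immunoprecipitation-efficiency differences between libraries distort
#' counts as a smooth, typically non-linear function of abundance; a single
#' scaling factor cannot remove them. Under the assumption that most windows
#' are not differentially enriched, the per-library trend of M on A is
#' estimated with a robust local-linear (tricube-weighted) loess fit and
#' returned as a windows x libraries offset matrix (log2 scale,
#' row-centered so offsets shift no per-window mean). Downstream GLM fitting
#' absorbs the offsets so that the post-normalization residual M trend is
#' approximately zero.
#'
#' @param wc [WindowCounts-class] restricted to filtered (kept) windows.
#' @param span loess span in (0, 1], default 0.3.
#' @param iterations robustness iterations of the symmetric family
#'   (default 4).
#' @param priorCount prior count for the underlying log2-CPM.
#' @param fitMask optional logical mask of windows the trend is fitted on;
#'   offsets are still predicted for every window. Used by the two-pass
#'   normalization to exclude windows already detected as differential,
#'   which would otherwise drag the trend and attenuate their own effect
#'   sizes wherever they locally dominate an abundance stratum.
#' @return numeric matrix of offsets, same dimensions as `counts(wc)`.
#' @export
loessNormalize <- function(wc, span = 0.3, iterations = 4,
                           priorCount = 0.5, fitMask = NULL) {
    if (span <= 0 || span > 1) stop("span must be in (0, 1]")
    l <- .log2Cpm(counts(wc), libSizes(wc), priorCount)
    ref <- rowMeans(l)
    if (is.null(fitMask)) fitMask <- rep(TRUE, nrow(l))
    if (sum(fitMask) < 50)
        stop("fewer than 50 windows to fit the normalization trend on")
    off <- matrix(0, nrow(l), ncol(l), dimnames = dimnames(l))
    trends <- vector("list", ncol(l))
    for (j in seq_len(ncol(l))) {
        Mj <- (l[, j] - ref)[fitMask]
        if (max(abs(Mj - mean(Mj))) < 1e-10) {
            ## degenerate (e.g. duplicated library): constant offset
            off[, j] <- mean(Mj)
            trends[[j]] <- local({
                v <- mean(Mj); function(a) rep(v, length(a))
            })
            next
        }
        fit <- tryCatch(
            loess(M ~ A,
                  data = data.frame(M = (l[, j] - ref)[fitMask],
                                    A = ref[fitMask]),
                  span = span, degree = 1, family = "symmetric",
                  control = stats::loess.control(surface = "interpolate",
                                                 statistics = "none",
                                                 iterations = iterations)),
            error = function(e)
                stop("loess fit failed (", conditionMessage(e),
                     "); too few windows for span ", span,
                     " - try a larger span"))
        pred <- predict(fit, newdata = data.frame(A = ref))
        if (anyNA(pred)) {
            ## windows outside the fitted A range: carry the edge value
            o <- order(ref[fitMask])
            pred[is.na(pred)] <- stats::approx(
                ref[fitMask][o], fit$fitted[o],
                xout = ref[is.na(pred)], rule = 2, ties = mean)$y
        }
        off[, j] <- pred
        trends[[j]] <- local({
            o <- order(ref[fitMask])
            stats::approxfun(ref[fitMask][o], fit$fitted[o],
                             rule = 2, ties = mean)
        })
    }
    out <- off - rowMeans(off)
    ## the per-library trend curves themselves (offset as a function of
    ## log2-CPM abundance); used for abundance-matched effect estimation
    attr(out, "trends") <- trends
    out
}

## normalized log2-CPM given loess offsets
.normLog2Cpm <- function(wc, offsets, priorCount = 0.5) {
    .log2Cpm(counts(wc), libSizes(wc), priorCount) - offsets
}

#' MDS embedding of libraries with outlier flagging
#'
#' The distance between two normalized libraries is the leading log-fold
#' change: the root-mean-square of the `topK` largest absolute per-window
#' log2 differences. Libraries are embedded in 2-D by classical
#' multidimensional scaling (double-centering + eigendecomposition). A
#' library is flagged as an outlier when its median distance to all other
#' libraries exceeds `outlierC` times the overall median pairwise distance.
#'
#' @param wc [WindowCounts-class] of filtered windows.
#' @param offsets loess offsets from [loessNormalize()] (or 0 for none).
#' @param topK number of largest differences entering the distance
#'   (default 500, capped at the window count).
#' @param outlierC outlier multiplier on the median pairwise distance
#'   (default 2).
#' @return list with `coordinates` (samples x 2 matrix), `distances`
#'   (symmetric matrix), and `outliers` (named logical vector).
#' @export
mdsQC <- function(wc, offsets = 0, topK = 500, outlierC = 2) {
    n <- ncol(wc)
    if (n < 3L) stop("mdsQC needs at least 3 samples")
    l <- .normLog2Cpm(wc, offsets)
    topK <- min(topK, nrow(l))
    d <- matrix(0, n, n, dimnames = list(colnames(l), colnames(l)))
    for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
        dif <- (l[, a] - l[, b])^2
        d[a, b] <- d[b, a] <-
            sqrt(mean(sort(dif, decreasing = TRUE)[seq_len(topK)]))
    }
    coords <- cmdscale(stats::as.dist(d), k = 2)
    colnames(coords) <- c("dim1", "dim2")
    medTo <- apply(d + diag(NA_real_, n), 1, median, na.rm = TRUE)
    overall <- median(d[upper.tri(d)])
    out <- if (overall > 0) medTo > outlierC * overall
           else rep(FALSE, n)
    list(coordinates = coords, distances = d,
         outliers = setNames(out, colnames(l)))
}
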