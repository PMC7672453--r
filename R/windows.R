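#' @importFrom GenomicRanges tileGenome slidingWindows countOverlaps reduce
#'   resize findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom utils head
NULL

#' Build a genome-grid of counting windows
#'
#' Tiles every declared chromosome with fixed-width windows. The default step
#' equals the width (non-overlapping tiling) so that window counts are
#' independent and merge gaps keep their plain bp meaning; a smaller step
#' yields overlapped sliding windows. Windows overlapping a blacklist are
#' dropped.
#'
#' @param genome `Seqinfo` declaration.
#' @param width window width in bp (default 150).
#' @param step distance between window starts (default `width`).
#' @param blacklist optional `GRanges` of regions to exclude.
#' @return `GRanges` of windows (last window per chromosome may be clipped).
#' @export
windowGrid <- function(genome, width = 150, step = width, blacklist = NULL) {
    if (width <= 0 || step <= 0) stop("width and step must be positive")
    chroms <- GRanges(seqnames(genome), IRanges(1L, seqlengths(genome)),
                      seqinfo = genome)
    win <- unlist(slidingWindows(chroms, width = as.integer(width),
                                 step = as.integer(step)))
    if (!is.null(blacklist) && length(blacklist))
        win <- win[!IRanges::overlapsAny(win, blacklist, ignore.strand = TRUE)]
    win
}

## extend single-end reads directionally to the expected fragment length;
## paired fragments (isFragment) pass through untouched
.toFragments <- function(reads, fragmentLength) {
    frag <- mcols(reads)$isFragment
    if (is.null(frag)) frag <- rep(FALSE, length(reads))
    se <- reads[!frag]
    if (length(se)) {
        strand(se)[strand(se) == "*"] <- "+"
        se <- suppressWarnings(
            resize(se, width = as.integer(fragmentLength), fix = "start"))
        if (!all(is.na(seqlengths(se)))) {
            over <- sum(start(se) < 1L |
                        end(se) > seqlengths(se)[as.character(seqnames(se))],
                        na.rm = TRUE)
            if (over > 0) {
                warning(over, " extended fragment(s) clipped at chromosome ends")
                se <- suppressWarnings(IRanges::trim(se))
            }
        }
    }
    c(se, reads[frag])
}

#' Count fragments in genome-grid windows
#'
#' Single-end reads are directionally extended to `fragmentLength` (147 bp by
#' default, the mononucleosome footprint); paired-end fragments are used
#' as-is. A fragment increments every window it overlaps by at least 1 bp.
#' Library sizes are the total number of counted fragments per library,
#' genome-wide.
#'
#' @param reads a named `list` of `GRanges` (one per library) as returned by
#'   [readAlignments()], or a single `GRanges` for a one-library experiment.
#' @param grid window `GRanges` from [windowGrid()].
#' @param fragmentLength extension length for single-end reads.
#' @return A [WindowCounts-class] object.
#' @export
countWindows <- function(reads, grid, fragmentLength = 147) {
    if (fragmentLength <= 0) stop("fragmentLength must be positive")
    if (!is.list(reads)) reads <- list(lib1 = reads)
    frags <- lapply(reads, .toFragments, fragmentLength = fragmentLength)
    cts <- vapply(frags, function(f)
        countOverlaps(grid, f, ignore.strand = TRUE),
        integer(length(grid)))
    if (length(grid) == 0L)
        cts <- matrix(integer(0), nrow = 0, ncol = length(frags))
    cts <- matrix(as.integer(cts), nrow = length(grid),
                  dimnames = list(NULL, names(reads)))
    WindowCounts(grid, cts, totals = vapply(frags, length, 1L))
}

#' Estimate the global background level from wide bins
#'
#' Fragments are counted in contiguous bins (default 2 kb) across the
#' genome; each bin's mean log2-CPM is rescaled by
#' `log2(windowWidth / binWidth)` so the background lives on the working
#' window scale, and the median rescaled bin abundance is the single global
#' background level used for window filtering.
#'
#' @param reads as in [countWindows()].
#' @param genome `Seqinfo`.
#' @param binWidth background bin width in bp (default 2000).
#' @param windowWidth the counting-window width the background is compared
#'   against (default 150).
#' @param fragmentLength extension length for single-end reads.
#' @return A [BackgroundModel-class] object.
#' @export
backgroundModel <- function(reads, genome, binWidth = 2000,
                            windowWidth = 150, fragmentLength = 147) {
    if (binWidth < windowWidth) stop("binWidth must be >= windowWidth")
    bins <- tileGenome(seqlengths(genome), tilewidth = as.integer(binWidth),
                       cut.last.tile.in.chrom = TRUE)
    if (length(bins) == 0L) stop("genome shorter than one background bin")
    bc <- countWindows(reads, bins, fragmentLength = fragmentLength)
    scaled <- abundance(bc) + log2(windowWidth / binWidth)
    new("BackgroundModel", binWidth = binWidth, windowWidth = windowWidth,
        binAbundance = scaled, globalBackground = stats::median(scaled))
}

#' Filter windows against the global background
#'
#' A window is kept iff its mean log2-CPM abundance exceeds the global
#' background by strictly more than `minLog2FC` (fold-change "over" the
#' threshold). Mark-specific defaults: 5 for H3K4me3, 7 for H3K27me3, 6 for
#' KDM1A (see [markProfile()]).
#'
#' @param wc [WindowCounts-class].
#' @param background [BackgroundModel-class] (or a scalar log2-CPM level).
#' @param minLog2FC non-negative log2 fold-change threshold.
#' @return logical keep-mask, one entry per window.
#' @export
filterWindows <- function(wc, background, minLog2FC = 5) {
    if (minLog2FC < 0) stop("minLog2FC must be >= 0")
    bg <- if (is(background, "BackgroundModel"))
        globalBackground(background) else as.numeric(background)
    (abundance(wc) - bg) > minLog2FC
}

#' Merge kept windows into enriched regions, splitting over-wide clusters
#'
#' Sorted windows whose inter-window gap is strictly less than `maxGap` join
#' one cluster. A cluster spanning `S > maxWidth` bp is split into
#' `ceiling(S / maxWidth)` sub-regions of near-equal width (each
#' `<= maxWidth`); member windows are assigned to sub-regions by midpoint.
#'
#' @param kept sorted `GRanges` of windows passing [filterWindows()].
#' @param maxGap merge windows closer than this many bp (default 200).
#' @param maxWidth maximum region width in bp (default 7000).
#' @param abundances optional per-window abundances, summarized per region.
#' @return `GRanges` of enriched regions with metadata columns `n_windows`
#'   and `abundance` (mean member-window abundance, `NA` when not supplied).
#' @export
mergeWindows <- function(kept, maxGap = 200, maxWidth = 7000,
                         abundances = NULL) {
    if (maxGap < 0) stop("maxGap must be >= 0")
    if (length(kept) == 0L)
        return(GRanges(n_windows = integer(0), abundance = numeric(0)))
    o <- order(as.character(seqnames(kept)), start(kept))
    if (!identical(o, seq_along(kept))) stop("windows must be sorted")
    if (maxWidth < max(width(kept))) stop("maxWidth must be >= window width")
    clusters <- reduce(kept, min.gapwidth = as.integer(maxGap),
                       ignore.strand = TRUE)
    hit <- findOverlaps(kept, clusters, ignore.strand = TRUE)
    clusterOf <- subjectHits(hit)[order(queryHits(hit))]
    mid <- (start(kept) + end(kept)) / 2
    ab <- if (is.null(abundances)) rep(NA_real_, length(kept))
          else as.numeric(abundances)
    pieces <- lapply(seq_along(clusters), function(i) {
        s <- start(clusters)[i]; e <- end(clusters)[i]
        span <- e - s + 1L
        k <- max(1L, as.integer(ceiling(span / maxWidth)))
        base <- span %/% k; rem <- span %% k
        w <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
        ends <- s - 1L + cumsum(w)
        starts <- c(s, head(ends, -1L) + 1L)
        memb <- which(clusterOf == i)
        pieceOf <- findInterval(mid[memb], starts)
        keepPiece <- sort(unique(pieceOf))
        GRanges(seqnames(clusters)[i],
                IRanges(starts[keepPiece], ends[keepPiece]),
                seqinfo = seqinfo(kept),
                n_windows = as.integer(tabulate(pieceOf, k)[keepPiece]),
                abundance = vapply(keepPiece, function(p)
                    mean(ab[memb[pieceOf == p]]), 1))
    })
    unname(do.call(c, pieces))
}

#' Mark-specific window/filter/merge parameter profiles
#'
#' Bundled defaults for the three supported marks: window width 150 bp for
#' all; log2 fold-change over background of 5 / 7 / 6, merge gaps of
#' 200 / 400 / 100 bp and maximum region widths of 7000 / 7000 / 2000 bp for
#' H3K4me3, H3K27me3 and KDM1A respectively.
#'
#' @param mark `"h3k4me3"`, `"h3k27me3"` or `"kdm1a"`.
#' @return a named list with `windowWidth`, `minLog2FC`, `maxGap`,
#'   `maxWidth`, `binWidth`, `fragmentLength`.
#' @export
markProfile <- function(mark = c("h3k4me3", "h3k27me3", "kdm1a")) {
    mark <- match.arg(mark)
    p <- switch(mark,
        h3k4me3  = list(minLog2FC = 5, maxGap = 200, maxWidth = 7000),
        h3k27me3 = list(minLog2FC = 7, maxGap = 400, maxWidth = 7000),
        kdm1a    = list(minLog2FC = 6, maxGap = 100, maxWidth = 2000))
    c(list(mark = mark, windowWidth = 150, binWidth = 2000,
           fragmentLength = 147), p)
}

#' Call enriched regions from aligned reads
#'
#' One-stop wrapper: build the window grid, count fragments, estimate the
#' global background, filter windows and merge the survivors into regions
#' under a mark profile.
#'
#' @param reads named list of per-library read `GRanges`.
#' @param genome `Seqinfo`.
#' @param profile a [markProfile()] list (possibly with overridden entries).
#' @param blacklist optional exclusion `GRanges`.
#' @return list with elements `regions` (`GRanges`), `windows`
#'   ([WindowCounts-class]), `keep` (logical mask) and `background`
#'   ([BackgroundModel-class]).
#' @export
callRegions <- function(reads, genome, profile = markProfile("h3k4me3"),
                        blacklist = NULL) {
    grid <- windowGrid(genome, width = profile$windowWidth,
                       blacklist = blacklist)
    wc <- countWindows(reads, grid, fragmentLength = profile$fragmentLength)
    bg <- backgroundModel(reads, genome, binWidth = profile$binWidth,
                          windowWidth = profile$windowWidth,
                          fragmentLength = profile$fragmentLength)
    keep <- filterWindows(wc, bg, minLog2FC = profile$minLog2FC)
    regions <- mergeWindows(windowRanges(wc)[keep], maxGap = profile$maxGap,
                            maxWidth = profile$maxWidth,
                            abundances = abundance(wc)[keep])
    list(regions = regions, windows = wc, keep = keep, background = bg)
}
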