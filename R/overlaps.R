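#' @importFrom stats fisher.test phyper
NULL

#' Call bivalent promoters from per-mark classifications
#'
#' A promoter is bivalent when it is enriched (any class above
#' `"unenriched"`) for both marks under each mark's own cutoff.
#'
#' @param k4Classes,k27Classes factors from [classifyEnrichment()], named
#'   by gene id (or any logical/character enrichment indicators named by
#'   gene id).
#' @return `DataFrame` with `gene_id`, `k4_enriched`, `k27_enriched`,
#'   `bivalent`, over the union of gene ids.
#' @export
callBivalent <- function(k4Classes, k27Classes) {
    asFlag <- function(x) {
        if (is.factor(x) || is.character(x))
            stats::setNames(as.character(x) != "unenriched", names(x))
        else stats::setNames(as.logical(x), names(x))
    }
    k4 <- asFlag(k4Classes); k27 <- asFlag(k27Classes)
    ids <- union(names(k4), names(k27))
    f4 <- ifelse(ids %in% names(k4), k4[ids], FALSE)
    f27 <- ifelse(ids %in% names(k27), k27[ids], FALSE)
    DataFrame(gene_id = ids, k4_enriched = unname(f4),
              k27_enriched = unname(f27),
              bivalent = unname(f4 & f27))
}

#' Fisher's exact test of overlap between two sets
#'
#' Builds the 2x2 table (in A / not in A) x (in B / not in B) over an
#' explicit universe and applies Fisher's exact test: the two-sided p-value
#' sums hypergeometric probabilities of tables (at fixed margins) no more
#' probable than the observed one; the reported `odds_ratio` is the
#' conditional maximum-likelihood estimate, and `sample_odds_ratio` the
#' plain cross-product ratio. The universe is a required argument: overlap
#' odds depend on it and the choice is the caller's to make (and log).
#'
#' @param setA,setB character vectors of element ids, subsets of `universe`.
#' @param universe character vector of all ids.
#' @return list with `table` (2x2 matrix), `odds_ratio`,
#'   `sample_odds_ratio`, `p_value`. With a zero margin the odds ratio is
#'   `NA` and p is 1.
#' @export
fisherOverlap <- function(setA, setB, universe) {
    universe <- unique(as.character(universe))
    setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stop("setA and setB must be subsets of the universe")
    a <- sum(setA %in% setB)
    b <- length(setA) - a
    cc <- length(setB) - a
    d <- length(universe) - a - b - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                  dimnames = list(inA = c("yes", "no"),
                                  inB = c("yes", "no")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(table = tab, odds_ratio = NA_real_,
                    sample_odds_ratio = NA_real_, p_value = 1))
    ft <- fisher.test(tab)
    list(table = tab,
         odds_ratio = unname(ft$estimate),
         sample_odds_ratio = (a * d) / (b * cc),
         p_value = ft$p.value)
}

#' Hypergeometric (upper-tail) enrichment p-value
#'
#' `P(X >= k)` where `X` counts members of a `setSize`-element set among
#' `classSize` draws without replacement from a universe of
#' `universeSize` elements.
#'
#' @param hitsInClass observed overlap `k`.
#' @param classSize number of draws.
#' @param setSize number of "marked" elements in the universe.
#' @param universeSize universe size.
#' @return upper-tail p-value.
#' @export
hypergeomEnrichment <- function(hitsInClass, classSize, setSize,
                                universeSize) {
    phyper(hitsInClass - 1, setSize, universeSize - setSize, classSize,
           lower.tail = FALSE)
}

#' Distance of regions to the nearest TSS, with binned proportions
#'
#' The distance of a region is 0 when any TSS lies inside it, otherwise the
#' minimum absolute distance from the region midpoint to a TSS (positions
#' only; strand is ignored). Distances are binned at the supplied breaks
#' (defaults 1, 5 and 10 kb) and proportions over bins sum to 1.
#'
#' @param regions `GRanges`.
#' @param tss TSS `GRanges`.
#' @param breaks strictly increasing distances in bp.
#' @return list with `distance` (per region) and `proportions` (named,
#'   summing to 1).
#' @export
tssDistanceAnnotation <- function(regions, tss,
                                  breaks = c(1000, 5000, 10000)) {
    if (is.unsorted(breaks, strictly = TRUE))
        stop("breaks must be strictly increasing")
    tssPos <- start(tss)
    tssChrom <- as.character(seqnames(tss))
    mid <- (start(regions) + end(regions)) %/% 2
    chrom <- as.character(seqnames(regions))
    dist <- vapply(seq_along(regions), function(i) {
        onChrom <- tssChrom == chrom[i]
        if (!any(onChrom)) return(Inf)
        pos <- tssPos[onChrom]
        if (any(pos >= start(regions)[i] & pos <= end(regions)[i]))
            return(0)
        min(abs(pos - mid[i]))
    }, 1)
    labs <- c(paste0("<", breaks[1]),
              if (length(breaks) > 1)
                  paste0(head(breaks, -1), "-", breaks[-1]),
              paste0(">", breaks[length(breaks)]))
    bin <- cut(dist, c(-1, breaks, Inf), labels = labs)
    prop <- table(bin) / max(length(regions), 1L)
    list(distance = dist, proportions = c(prop))
}

#' Fraction of one set covered by another
#'
#' For character id sets, `|A intersect B| / |A|`; for `GRanges`, the
#' fraction of `a` ranges overlapping `b` by at least 1 bp.
#'
#' @param a,b both character vectors (gene ids) or both `GRanges`.
#' @return a fraction in `[0, 1]` (`NaN` for an empty `a`).
#' @export
overlapFraction <- function(a, b) {
    if (is(a, "GRanges")) {
        if (length(a) == 0L) return(NaN)
        mean(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
    } else {
        a <- unique(as.character(a))
        if (length(a) == 0L) return(NaN)
        mean(a %in% as.character(b))
    }
}
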