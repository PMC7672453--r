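#' @importFrom stats density quantile
#' @importFrom Biostrings DNAStringSet letterFrequency
#'   dinucleotideFrequency
NULL

#' Quantify promoter abundance as log2(mean count + 8)
#'
#' Counts fragments per library in each promoter (TSS +/- `radius`), takes
#' the mean raw count across libraries, and transforms to
#' `log2(mean + 8)` — the pseudo-count of 8 stabilizes lowly covered
#' promoters and puts different marks on a comparable scale. The floor of
#' the transform is 3 (`log2(8)`) at zero coverage.
#'
#' @param reads named list of per-library read `GRanges` (single-end reads
#'   are extended to `fragmentLength`), or a [WindowCounts-class] whose
#'   window counts are summed within each promoter.
#' @param tss TSS annotation `GRanges`.
#' @param radius promoter half-width (default 1000).
#' @param fragmentLength extension length for read input.
#' @return `DataFrame` with `gene_id`, `mean_count`, `log_abundance`.
#' @export
promoterCounts <- function(reads, tss, radius = 1000,
                           fragmentLength = 147) {
    prom <- promoterRanges(tss, radius)
    if (is(reads, "WindowCounts")) {
        hit <- findOverlaps(prom, windowRanges(reads), ignore.strand = TRUE)
        cts <- matrix(0, length(prom), ncol(reads))
        y <- counts(reads)
        for (j in seq_len(ncol(y))) {
            sums <- tapply(y[subjectHits(hit), j], queryHits(hit), sum)
            cts[as.integer(names(sums)), j] <- sums
        }
    } else {
        if (!is.list(reads)) reads <- list(lib1 = reads)
        frags <- lapply(reads, .toFragments, fragmentLength = fragmentLength)
        cts <- vapply(frags, function(f)
            countOverlaps(prom, f, ignore.strand = TRUE),
            integer(length(prom)))
        cts <- matrix(cts, nrow = length(prom))
    }
    meanCount <- rowMeans(cts)
    DataFrame(gene_id = mcols(prom)$gene_id,
              mean_count = meanCount,
              log_abundance = log2(meanCount + 8))
}

#' Enrichment cutoff from the local minimum of a bimodal density
#'
#' Promoter abundances for a genuinely bound mark separate into an
#' unenriched and an enriched mode; the cutoff between them is the density
#' minimum between the two modes. A Gaussian KDE (Silverman's bandwidth by
#' default) is evaluated on a 512-point grid; the cutoff is the grid argmin
#' strictly between the two highest local maxima. When the density is not
#' bimodal the function refuses and asks for a user-supplied cutoff
#' (`userCutoff`), which is recorded with provenance `"user_supplied"`.
#'
#' @param logAbundances numeric vector of `log2(mean + 8)` values
#'   (>= 200 values required for the KDE route).
#' @param bw bandwidth specification passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @param adjust bandwidth multiplier.
#' @param userCutoff optional numeric; bypasses the KDE entirely.
#' @return list with `cutoff`, `provenance`
#'   (`"bimodal_minimum"` or `"user_supplied"`), and `bandwidth`
#'   (`NA` for user-supplied).
#' @export
bimodalCutoff <- function(logAbundances, bw = "nrd0", adjust = 1,
                          userCutoff = NULL) {
    if (!is.null(userCutoff)) {
        return(list(cutoff = as.numeric(userCutoff),
                    provenance = "user_supplied", bandwidth = NA_real_))
    }
    x <- logAbundances[is.finite(logAbundances)]
    if (length(x) < 200)
        stop("need at least 200 abundance values for a stable density")
    d <- density(x, bw = bw, adjust = adjust, n = 512)
    y <- d$y
    isMax <- c(FALSE, y[2:511] > y[1:510] & y[2:511] > y[3:512], FALSE)
    peaks <- which(isMax)
    if (length(peaks) < 2L)
        stop("abundance density is not bimodal; supply userCutoff= ",
             "(e.g. chosen by inspecting the distribution against ",
             "CpG density)")
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    between <- seq(top2[1] + 1L, top2[2] - 1L)
    cut <- d$x[between[which.min(y[between])]]
    list(cutoff = cut, provenance = "bimodal_minimum", bandwidth = d$bw)
}

#' Classify promoters into unenriched / low / intermediate / high
#'
#' Promoters below the cutoff are unenriched. Enriched promoters are split
#' by the 25th and 75th percentiles of the enriched-set abundance: the
#' lowest quarter is `low`, the highest quarter `high`, the two middle
#' quarters `intermediate`. Values exactly on a quartile boundary go to the
#' inner (`intermediate`) class; if all enriched values are tied, all are
#' `intermediate`.
#'
#' @param abundances `DataFrame` from [promoterCounts()] or a numeric
#'   vector of log-abundances.
#' @param cutoff a [bimodalCutoff()] result or a numeric threshold.
#' @return factor with levels `unenriched`, `low`, `intermediate`, `high`
#'   (named by `gene_id` when available).
#' @export
classifyEnrichment <- function(abundances, cutoff) {
    if (is.list(cutoff)) cutoff <- cutoff$cutoff
    ids <- NULL
    if (is(abundances, "DataFrame") || is.data.frame(abundances)) {
        ids <- abundances$gene_id
        abundances <- abundances$log_abundance
    }
    cls <- rep("unenriched", length(abundances))
    enr <- abundances >= cutoff
    if (!any(enr)) {
        warning("no promoter above the enrichment cutoff")
    } else {
        q <- quantile(abundances[enr], c(0.25, 0.75), names = FALSE)
        cls[enr] <- "intermediate"
        cls[enr & abundances < q[1]] <- "low"
        cls[enr & abundances > q[2]] <- "high"
    }
    f <- factor(cls, levels = c("unenriched", "low", "intermediate", "high"))
    if (!is.null(ids)) names(f) <- ids
    f
}

#' Observed/expected CpG density
#'
#' Gardiner-Garden measure: `(N_CpG / (N_C * N_G)) * L`, where counts are
#' case-insensitive and `L` counts only unambiguous A/C/G/T letters.
#' Returns 0 when the sequence has no C or no G.
#'
#' @param sequence a character vector or
#'   [Biostrings::DNAStringSet] of promoter sequences.
#' @return numeric vector of observed/expected CpG ratios.
#' @examples
#' cpgDensity("CGCGCG")  # 2
#' @export
cpgDensity <- function(sequence) {
    if (!is(sequence, "DNAStringSet"))
        sequence <- DNAStringSet(toupper(as.character(sequence)))
    nC <- as.numeric(letterFrequency(sequence, "C"))
    nG <- as.numeric(letterFrequency(sequence, "G"))
    L <- as.numeric(letterFrequency(sequence, "ACGT"))
    nCG <- as.numeric(dinucleotideFrequency(sequence)[, "CG"])
    ifelse(nC * nG == 0, 0, nCG * L / (nC * nG))
}
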