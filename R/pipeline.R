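#' @importFrom jsonlite write_json
NULL

.writeTsv <- function(x, path) {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Run the full window-differential analysis
#'
#' Executes the stages in order — window counting, region calling, loess
#' normalization, MDS QC (flag-then-drop of outlier libraries with an
#' explicit re-normalization), per-window NB tests for each non-control
#' condition against the control, Simes promoter combination with BH
#' correction, promoter enrichment classification with bivalency calls, and
#' overlap statistics — writing a TSV/BED per stage plus a JSON manifest of
#' parameters, excluded samples and row counts that suffices to reproduce
#' the run.
#'
#' Conditions are parsed from library names of the form
#' `"<condition>_<replicate>"` unless given explicitly; the control is the
#' first condition level. When a tested contrast has a group with a single
#' replicate, dispersions are estimated from the conditions that do have
#' replicates and shared across the contrast (with a logged warning).
#'
#' @param k4Reads named list of per-library read `GRanges` for the primary
#'   (tested) mark.
#' @param tss TSS annotation `GRanges`.
#' @param genome `Seqinfo`.
#' @param outDir output directory (created if needed).
#' @param k27Reads optional named list for the second mark, enabling
#'   bivalency classification.
#' @param conditions optional character vector of condition labels per
#'   `k4Reads` library; default parses names at `"_"`.
#' @param control control condition label (default first in order of
#'   appearance).
#' @param profile,k27Profile [markProfile()] lists for the two marks.
#' @param blacklist optional exclusion `GRanges`.
#' @param alpha FDR threshold for differential calls (default 0.2).
#' @param radius promoter half-width (default 1000).
#' @param span loess span (default 0.3).
#' @param topK,outlierC MDS QC parameters.
#' @param dropOutliers drop MDS-flagged libraries and re-normalize
#'   (default `TRUE`; the flagging is always reported in the manifest).
#' @param writeTracks also write RPKM bedGraph tracks (10 bp bins; off by
#'   default, it is the slowest stage).
#' @param userCutoffs optional named list of user-supplied classification
#'   cutoffs, e.g. `list(k4 = 6.5)`, for non-bimodal densities.
#' @return (invisibly) a list with the principal in-memory results:
#'   `regions`, `qc`, `tests` (per contrast), `promoters` (per contrast),
#'   `classes`, `bivalent`, `overlaps`, `manifest`.
#' @export
runPipeline <- function(k4Reads, tss, genome, outDir,
                        k27Reads = NULL,
                        conditions = NULL, control = NULL,
                        profile = markProfile("h3k4me3"),
                        k27Profile = markProfile("h3k27me3"),
                        blacklist = NULL,
                        alpha = 0.2, radius = 1000, span = 0.3,
                        topK = 500, outlierC = 2,
                        dropOutliers = TRUE, writeTracks = FALSE,
                        userCutoffs = list()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(conditions))
        conditions <- sub("_[^_]*$", "", names(k4Reads))
    if (is.null(control)) control <- conditions[1]
    conditions <- factor(conditions,
                         levels = c(control, setdiff(unique(conditions),
                                                     control)))
    condAll <- as.character(conditions)   # aligned with names(k4Reads)
    manifest <- list(parameters = list(
        profile = profile, alpha = alpha, radius = radius, span = span,
        topK = topK, outlierC = outlierC, control = control,
        libraries = names(k4Reads), conditions = as.character(conditions)),
        stages = list())
    addStage <- function(name, rows, extra = list()) {
        manifest$stages[[name]] <<- c(list(rows = rows), extra)
    }

    ## 1-2: counting + region calling
    rc <- callRegions(k4Reads, genome, profile = profile,
                      blacklist = blacklist)
    addStage("count", nrow(rc$windows))
    writeBed(rc$regions, file.path(outDir, "regions_k4.bed"))
    addStage("regions", length(rc$regions),
             list(background = globalBackground(rc$background)))

    ## 3: loess normalization on kept windows
    wcK <- rc$windows[rc$keep, ]
    offsets <- loessNormalize(wcK, span = span)
    addStage("normalize", nrow(wcK))

    ## 4: MDS QC, flag-then-drop with explicit re-run
    qc <- mdsQC(wcK, offsets, topK = topK, outlierC = outlierC)
    excluded <- names(which(qc$outliers))
    if (dropOutliers && length(excluded)) {
        keepLib <- !(names(k4Reads) %in% excluded)
        message("excluding outlier librar",
                if (sum(!keepLib) > 1) "ies: " else "y: ",
                paste(excluded, collapse = ", "))
        wcK <- wcK[, keepLib]
        conditions <- droplevels(conditions[keepLib])
        offsets <- loessNormalize(wcK, span = span)
    }
    addStage("qc", ncol(wcK), list(excluded = excluded))
    .writeTsv(data.frame(library = rownames(qc$coordinates),
                         qc$coordinates,
                         outlier = qc$outliers),
              file.path(outDir, "mds_qc.tsv"))

    ## 5-6: per-contrast window tests, Simes + BH at promoters
    others <- setdiff(levels(conditions), control)
    tests <- list(); proms <- list()
    sharedDisp <- NULL
    for (cond in others) {
        sel <- conditions %in% c(control, cond)
        grp <- droplevels(conditions[sel])
        disp <- NULL
        if (min(table(grp)) < 2L) {
            warning("contrast ", cond, " vs ", control,
                    " has a single-replicate group; using dispersions ",
                    "estimated from replicated conditions")
            if (is.null(sharedDisp)) {
                repCond <- names(which(table(conditions) >= 2L))
                selR <- conditions %in% repCond
                sharedDisp <- estimateWindowDispersion(
                    wcK[, selR], offsets[, selR, drop = FALSE],
                    droplevels(conditions[selR]))
            }
            disp <- sharedDisp
        }
        wcSel <- wcK[, sel]
        if (is.null(disp))   # estimate once, reuse across passes
            disp <- estimateWindowDispersion(wcSel,
                                             offsets[, sel, drop = FALSE],
                                             grp)
        res <- testWindows(wcSel, offsets[, sel, drop = FALSE],
                           group = grp, dispersion = disp)
        ## iterated normalization: windows near candidate differential
        ## promoters are excluded from the trend fit and the contrast is
        ## re-tested, so detected signal cannot drag the trend and
        ## attenuate its own effect sizes
        for (pass in 1:2) {
            cand <- simesCombine(res, tss, radius = radius)
            ## generous candidate rule (raw Simes p): missing a genuinely
            ## differential promoter costs far more than excluding a few
            ## null ones from the trend fit
            candTss <- tss[tss$gene_id %in%
                           cand$gene_id[cand$simes_p < 0.05]]
            flag <- IRanges::overlapsAny(windowRanges(wcSel), candTss,
                                         maxgap = radius + 300)
            if (sum(flag) < 20 || sum(!flag) < 200) break
            off2 <- loessNormalize(wcSel, span = span, fitMask = !flag)
            res <- testWindows(wcSel, off2, group = grp, dispersion = disp)
        }
        pr <- callDifferential(simesCombine(res, tss, radius = radius),
                               alpha = alpha)
        tests[[cond]] <- res
        proms[[cond]] <- pr
        .writeTsv(as.data.frame(res),
                  file.path(outDir, sprintf("windows_%s_vs_%s.tsv",
                                            cond, control)))
        .writeTsv(pr, file.path(outDir, sprintf("promoters_%s_vs_%s.tsv",
                                                cond, control)))
    }
    addStage("test", sum(vapply(tests, length, 1L)))
    addStage("combine", sum(vapply(proms, nrow, 1L)),
             list(differential = lapply(proms, function(p)
             sum(p$is_differential))))

    ## 7: promoter classification (control libraries) + bivalency
    ctrlLibs <- k4Reads[condAll == control &
                        !(names(k4Reads) %in% excluded)]
    pcK4 <- promoterCounts(ctrlLibs, tss, radius = radius,
                           fragmentLength = profile$fragmentLength)
    cutK4 <- bimodalCutoff(pcK4$log_abundance,
                           userCutoff = userCutoffs$k4)
    clsK4 <- classifyEnrichment(pcK4, cutK4)
    classes <- DataFrame(gene_id = pcK4$gene_id,
                         k4_log_abundance = pcK4$log_abundance,
                         k4_class = clsK4)
    bivalent <- NULL
    if (!is.null(k27Reads)) {
        ctrl27 <- k27Reads[sub("_[^_]*$", "", names(k27Reads)) == control]
        pcK27 <- promoterCounts(ctrl27, tss, radius = radius,
                                fragmentLength = k27Profile$fragmentLength)
        cutK27 <- bimodalCutoff(pcK27$log_abundance,
                                userCutoff = userCutoffs$k27)
        clsK27 <- classifyEnrichment(pcK27, cutK27)
        classes$k27_log_abundance <- pcK27$log_abundance
        classes$k27_class <- clsK27
        bivalent <- callBivalent(clsK4, clsK27)
        .writeTsv(bivalent, file.path(outDir, "bivalent.tsv"))
    }
    .writeTsv(classes, file.path(outDir, "promoter_classes.tsv"))
    addStage("classify", nrow(classes),
             list(cutoff_k4 = cutK4$cutoff,
                  cutoff_k4_provenance = cutK4$provenance))

    ## 8: overlap statistics
    universe <- as.character(tss$gene_id)
    overlaps <- list()
    diffSets <- lapply(proms, function(p)
        p$gene_id[p$is_differential])
    if (length(diffSets) >= 2L) {
        a <- diffSets[[others[1]]]; b <- diffSets[[others[2]]]
        overlaps$overlap_fraction <- overlapFraction(b, a)
    }
    if (!is.null(bivalent) && length(diffSets)) {
        bivIds <- bivalent$gene_id[bivalent$bivalent]
        overlaps$bivalent_fisher <- lapply(diffSets, function(s)
            fisherOverlap(s, bivIds, universe))
    }
    overlaps$tss_distance <-
        tssDistanceAnnotation(rc$regions, tss)$proportions
    addStage("overlaps", length(overlaps))

    if (writeTracks) {
        for (nm in names(k4Reads)) {
            cov <- coverageRpkm(k4Reads[[nm]], genome,
                                fragmentLength = profile$fragmentLength,
                                label = nm)
            writeBedGraph(cov, mcols(cov)$score,
                          file.path(outDir, paste0("track_", nm,
                                                   ".bedGraph")),
                          merge = TRUE, trackName = nm)
        }
        addStage("tracks", length(k4Reads))
    }

    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(regions = rc$regions, windows = rc$windows,
                   keep = rc$keep, qc = qc, offsets = offsets,
                   tests = tests, promoters = proms, classes = classes,
                   bivalent = bivalent, overlaps = overlaps,
                   manifest = manifest))
}
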