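#' @importFrom stats rlnorm rnbinom rpois runif
NULL

#' Configure a synthetic ChIP-seq experiment
#'
#' Builds a [SimConfig-class] describing the architecture the generator
#' plants: a single-chromosome genome; promoters with TSSs at least 5 kb
#' apart; a two-component log-normal abundance mixture (unenriched vs
#' enriched); fractions of promoters enriched for H3K4me3, H3K27me3 and for
#' both (bivalent); three conditions (control `CRwt`, transgenic `TG`,
#' non-transgenic descendant `nonTG`) with replicate libraries; planted
#' differential promoters in TG and nonTG with |log2FC| drawn from
#' `lfcRange`, a sign mix favouring gains, and a configured overlap between
#' the nonTG and TG differential sets; a smooth monotone per-library
#' immunoprecipitation-efficiency bias; negative-binomial replicate noise;
#' uniform genomic background; and, optionally, one outlier replicate with
#' 10x dispersion.
#'
#' @param seed integer master seed; per-library substreams are derived from
#'   it so adding a library never perturbs the others.
#' @param genomeLength length in bp of the single simulated chromosome.
#' @param nPromoters number of promoters.
#' @param fracK4,fracK27,fracBivalent planted enrichment fractions
#'   (bivalent is a subset of both marks).
#' @param meanlogLow,sdlogLow,meanlogHigh,sdlogHigh log-normal parameters of
#'   the unenriched / enriched abundance components (expected fragments per
#'   promoter per library at size factor 1).
#' @param conditions,replicates condition labels (control first) and
#'   replicates per condition.
#' @param nDifferential,nDifferentialNonTG planted differential promoter
#'   counts for the TG and nonTG contrasts.
#' @param lfcRange,fracGain |log2FC| range and fraction of gains.
#' @param overlapNonTG fraction of the nonTG differential set shared with
#'   the TG set.
#' @param bivalentDiffWeight sampling weight of bivalent promoters when
#'   drawing differential sets (< 1 depletes them).
#' @param dispersion NB dispersion of replicate noise.
#' @param backgroundRate background fragments per kb per library.
#' @param libSizeFactorRange range of per-library size factors.
#' @param biasAmplitude maximum |amplitude| of the per-library bias.
#' @param outlierReplicate plant one outlier replicate (TG_A, 10x
#'   dispersion).
#' @param fragmentLength,readLength,mapqFailRate fragment / read geometry
#'   and the fraction of reads drawn below the MAPQ-above-20 filter.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      genomeLength = 12e6,
                      nPromoters = 2000,
                      fracK4 = 0.55, fracK27 = 0.25, fracBivalent = 0.15,
                      meanlogLow = log(3), sdlogLow = 0.6,
                      meanlogHigh = log(350), sdlogHigh = 0.5,
                      conditions = c("CRwt", "TG", "nonTG"),
                      replicates = 3L,
                      nDifferential = 300L, nDifferentialNonTG = 120L,
                      lfcRange = c(1, 3), fracGain = 0.8,
                      overlapNonTG = 0.75,
                      bivalentDiffWeight = 0.15,
                      dispersion = 0.05,
                      backgroundRate = 0.05,
                      libSizeFactorRange = c(0.8, 1.25),
                      biasAmplitude = 0.5,
                      outlierReplicate = FALSE,
                      fragmentLength = 147L, readLength = 100L,
                      mapqFailRate = 0.02) {
    stopifnot(fracK4 <= 1, fracK27 <= 1, fracBivalent <= min(fracK4, fracK27),
              overlapNonTG >= 0, overlapNonTG <= 1, fracGain >= 0,
              fracGain <= 1, dispersion > 0)
    new("SimConfig", seed = as.integer(seed),
        genome = genomeDeclaration("chrS", as.integer(genomeLength)),
        nPromoters = as.integer(nPromoters),
        fracK4 = fracK4, fracK27 = fracK27, fracBivalent = fracBivalent,
        meanlogLow = meanlogLow, sdlogLow = sdlogLow,
        meanlogHigh = meanlogHigh, sdlogHigh = sdlogHigh,
        conditions = conditions, replicates = as.integer(replicates),
        nDifferential = as.integer(nDifferential),
        nDifferentialNonTG = as.integer(nDifferentialNonTG),
        lfcRange = lfcRange, fracGain = fracGain,
        overlapNonTG = overlapNonTG,
        bivalentDiffWeight = bivalentDiffWeight,
        dispersion = dispersion, backgroundRate = backgroundRate,
        libSizeFactorRange = libSizeFactorRange,
        biasAmplitude = biasAmplitude,
        outlierReplicate = outlierReplicate,
        fragmentLength = as.integer(fragmentLength),
        readLength = as.integer(readLength),
        mapqFailRate = mapqFailRate)
}

## smooth monotone IP-efficiency distortion of expected counts:
## log mu' = log mu + b * logistic((log mu - x0) / s), a saturating step -
## enrichment-dependent capture efficiency that plateaus at high occupancy.
## The transition is centered on the enriched abundance component (x0, s
## from the configured mixture), so the curve is clearly non-linear across
## the filtered abundance range (a single scaling factor cannot remove it)
## yet approaches unit slope at the top, leaving planted fold changes
## between strongly enriched promoters essentially undistorted. Monotone
## for |b| < 4 s.
.biasTransform <- function(mu, b, x0, s) {
    x <- log(pmax(mu, 1e-12))
    exp(x + b * stats::plogis((x - x0) / s))
}

#' Simulate the genome, TSS annotation, promoter sequences and truth
#'
#' Places `nPromoters` TSSs at least 5 kb apart on the simulated
#' chromosome, assigns planted enrichment flags / mixture components / base
#' abundances / differential effects, derives per-library bias amplitudes
#' and size factors, and draws promoter sequences with elevated G+C and
#' unsuppressed CpG for enriched promoters (so the CpG-density /
#' enrichment relationship of real promoters is reproducible).
#'
#' @param config a [simConfig()] object.
#' @param sequences generate promoter sequences (set `FALSE` to skip the
#'   slowest part when sequences are not needed).
#' @return list with `genome` (`Seqinfo`), `tss` (`GRanges`), `sequences`
#'   (`DNAStringSet` or `NULL`) and `truth` ([SimTruth-class]).
#' @export
simulateAnnotation <- function(config, sequences = TRUE) {
    set.seed(config@seed)
    n <- config@nPromoters
    L <- seqlengths(config@genome)[[1]]
    gap <- 5000
    slack <- L - 2 * gap - (n - 1) * gap
    if (slack < 0) stop("genome too short for ", n, " TSSs >= 5 kb apart")
    tssPos <- gap + sort(round(runif(n, 0, slack))) +
        (seq_len(n) - 1L) * gap
    ids <- sprintf("gene%04d", seq_len(n))
    tss <- tssAnnotation(ids, "chrS", tssPos,
                         strand = sample(c("+", "-"), n, TRUE),
                         genome = config@genome)

    ## planted enrichment architecture
    nBiv <- round(config@fracBivalent * n)
    nK4 <- round(config@fracK4 * n)
    nK27 <- round(config@fracK27 * n)
    biv <- sample(n, nBiv)
    k4 <- c(biv, sample(setdiff(seq_len(n), biv), nK4 - nBiv))
    k27 <- c(biv, sample(setdiff(seq_len(n), k4), nK27 - nBiv))
    isK4 <- seq_len(n) %in% k4
    isK27 <- seq_len(n) %in% k27
    isBiv <- seq_len(n) %in% biv
    drawBase <- function(enriched)
        ifelse(enriched,
               rlnorm(n, config@meanlogHigh, config@sdlogHigh),
               rlnorm(n, config@meanlogLow, config@sdlogLow))
    baseK4 <- drawBase(isK4)
    baseK27 <- drawBase(isK27)

    ## differential sets, depleting bivalent promoters
    if (config@nDifferential > sum(isK4) ||
        config@nDifferentialNonTG > sum(isK4))
        stop("differential set larger than the K4-enriched promoter pool")
    wt <- ifelse(isBiv, config@bivalentDiffWeight, 1)
    pick <- function(pool, size, prob = NULL) {
        if (size <= 0L || length(pool) == 0L) return(integer(0))
        pool[sample.int(length(pool), size, prob = prob)]
    }
    k4Idx <- which(isK4)
    diffTG <- pick(k4Idx, config@nDifferential, wt[k4Idx])
    nShared <- round(config@overlapNonTG * config@nDifferentialNonTG)
    shared <- pick(diffTG, min(nShared, length(diffTG)))
    poolNon <- setdiff(k4Idx, diffTG)
    extra <- pick(poolNon, config@nDifferentialNonTG - length(shared),
                  wt[poolNon])
    diffNonTG <- c(shared, extra)
    drawLfc <- function(idx, signs = NULL) {
        out <- numeric(n)
        mag <- runif(length(idx), config@lfcRange[1], config@lfcRange[2])
        if (is.null(signs))
            signs <- ifelse(runif(length(idx)) < config@fracGain, 1, -1)
        out[idx] <- signs * mag
        out
    }
    lfcTG <- drawLfc(diffTG)
    ## shared promoters keep the TG sign (correlated inheritance),
    ## nonTG-exclusive promoters draw a fresh sign
    signNon <- c(sign(lfcTG[shared]),
                 ifelse(runif(length(extra)) < config@fracGain, 1, -1))
    lfcNonTG <- drawLfc(diffNonTG, signs = signNon)

    prom <- tss
    mcols(prom) <- DataFrame(gene_id = ids, k4 = isK4, k27 = isK27,
                             bivalent = isBiv,
                             baseK4 = baseK4, baseK27 = baseK27,
                             diffTG = seq_len(n) %in% diffTG,
                             diffNonTG = seq_len(n) %in% diffNonTG,
                             lfcTG = lfcTG, lfcNonTG = lfcNonTG)
    names(prom) <- ids

    ## per-library layout with deterministic substream seeds
    libs <- expand.grid(replicate = LETTERS[seq_len(config@replicates)],
                        condition = config@conditions,
                        stringsAsFactors = FALSE)[, 2:1]
    libName <- paste(libs$condition, libs$replicate, sep = "_")
    nLib <- nrow(libs)
    ## IP-efficiency bias drifts with processing order (libraries prepared
    ## condition by condition), spanning [-amplitude, +amplitude]; the
    ## deterministic gradient guarantees a consequential between-condition
    ## component, as in real batch-processed experiments
    biasSeq <- if (nLib > 1)
        seq(-config@biasAmplitude, config@biasAmplitude,
            length.out = nLib) else 0
    libDf <- DataFrame(
        name = libName, condition = libs$condition,
        replicate = libs$replicate,
        biasAmplitude = biasSeq,
        sizeFactor = runif(nLib, config@libSizeFactorRange[1],
                           config@libSizeFactorRange[2]),
        outlier = config@outlierReplicate &
            libName == paste0(config@conditions[2], "_A"),
        substream = config@seed + 1000L + seq_len(nLib))
    truth <- new("SimTruth", promoters = prom, libraries = libDf,
                 seed = config@seed)

    seqs <- NULL
    if (sequences) {
        enrichedAny <- isK4 | isK27
        seqs <- DNAStringSet(vapply(seq_len(n), function(i)
            .promoterSequence(2000L, enrichedAny[i]), ""))
        names(seqs) <- ids
    }
    list(genome = config@genome, tss = tss, sequences = seqs, truth = truth)
}

## CpG-rich sequence for enriched promoters, CpG-suppressed otherwise
.promoterSequence <- function(len, enriched) {
    base <- c("A", "C", "G", "T")
    if (enriched) {
        s <- sample(base, len, TRUE, prob = c(0.225, 0.275, 0.275, 0.225))
    } else {
        s <- sample(base, len, TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
        cg <- which(s[-len] == "C" & s[-1] == "G")
        kill <- cg[runif(length(cg)) < 0.85]
        if (length(kill))
            s[kill + 1L] <- sample(c("A", "T"), length(kill), TRUE)
    }
    paste(s, collapse = "")
}

#' Simulate per-library aligned fragments
#'
#' For each library, realized per-promoter fragment counts are drawn from a
#' negative binomial whose mean is the size-factor-scaled base abundance
#' times `2^lfc` for the library's condition, passed through the library's
#' smooth monotone IP-bias curve; fragment start positions are uniform
#' within TSS +/- 1 kb. Background fragments are uniform genome-wide at the
#' configured per-kb rate. MAPQ values are drawn so that about
#' `mapqFailRate` of reads fall at or below 20. Each library uses its own
#' seed substream, so outputs are byte-identical under a fixed master seed.
#'
#' @param config a [simConfig()].
#' @param truth the [SimTruth-class] from [simulateAnnotation()].
#' @param mark `"h3k4me3"` (single-end-style fragments; differential
#'   effects planted) or `"h3k27me3"` (paired-end-style fragments flagged
#'   `isFragment`; no differential effects).
#' @return named list of per-library `GRanges` with `mapq`, `isDuplicate`,
#'   `isFragment` metadata, ready for [countWindows()].
#' @export
simulateReads <- function(config, truth, mark = c("h3k4me3", "h3k27me3")) {
    mark <- match.arg(mark)
    prom <- truth@promoters
    libs <- truth@libraries
    L <- seqlengths(config@genome)[[1]]
    base <- if (mark == "h3k4me3") prom$baseK4 else prom$baseK27
    markOff <- if (mark == "h3k4me3") 0L else 500000L
    out <- vector("list", nrow(libs))
    names(out) <- libs$name
    for (j in seq_len(nrow(libs))) {
        set.seed(libs$substream[j] + markOff)
        lfc <- if (mark != "h3k4me3") 0
               else switch(libs$condition[j],
                           TG = prom$lfcTG, nonTG = prom$lfcNonTG, 0)
        mu <- .biasTransform(base * 2^lfc * libs$sizeFactor[j],
                             libs$biasAmplitude[j],
                             config@meanlogHigh, config@sdlogHigh * 1.5)
        phi <- config@dispersion * if (libs$outlier[j]) 10 else 1
        k <- rnbinom(length(mu), mu = mu, size = 1 / phi)
        tss0 <- start(prom) - 1L
        starts0 <- unlist(lapply(which(k > 0), function(i)
            tss0[i] - 1000L +
                floor(runif(k[i], 0, 2000 - config@fragmentLength))),
            use.names = FALSE)
        if (is.null(starts0)) starts0 <- integer(0)
        nBg <- rpois(1, config@backgroundRate * L / 1000)
        bg0 <- floor(runif(nBg, 0, L - config@fragmentLength))
        all0 <- c(starts0, bg0)
        nFrag <- length(all0)
        mapq <- ifelse(runif(nFrag) < config@mapqFailRate, 15L, 35L)
        gr <- GRanges(rep("chrS", nFrag),
                      IRanges(all0 + 1L, width = config@fragmentLength),
                      strand = sample(c("+", "-"), nFrag, TRUE),
                      mapq = mapq, isDuplicate = rep(FALSE, nFrag),
                      isFragment = rep(mark == "h3k27me3", nFrag),
                      seqinfo = config@genome)
        out[[j]] <- sort(gr, ignore.strand = TRUE)
    }
    out
}

#' Simulate window-level counts directly (matrix-level generator)
#'
#' A faster companion to [simulateReads()] for calibration studies that do
#' not need read-level structure: 150 bp windows tiling each promoter get
#' negative-binomial counts whose expectations spread the promoter's biased
#' expected abundance uniformly over its windows, plus background. The
#' noise model (NB dispersion, size factors, bias curves, planted effects,
#' outlier replicate) matches the read-level generator.
#'
#' @param config a [simConfig()].
#' @param truth a [SimTruth-class].
#' @param mark which mark's base abundances and effects to use.
#' @param windowWidth window width in bp.
#' @return a [WindowCounts-class] of promoter windows; `rowData()` carries
#'   the owning `gene_id`.
#' @export
simulateWindowCounts <- function(config, truth, mark = "h3k4me3",
                                 windowWidth = 150) {
    prom <- truth@promoters
    libs <- truth@libraries
    n <- length(prom)
    nWin <- (2000L %/% windowWidth)
    ## windows tile [tss-1000, tss-1000 + nWin*width)
    winStart <- rep(start(prom) - 1000L, each = nWin) +
        rep(seq_len(nWin) - 1L, n) * windowWidth
    win <- GRanges("chrS", IRanges(winStart, width = windowWidth),
                   seqinfo = config@genome)
    mcols(win)$gene_id <- rep(prom$gene_id, each = nWin)
    base <- if (mark == "h3k4me3") prom$baseK4 else prom$baseK27
    ## fragment-overlap weight: a 147 bp fragment overlaps a 150 bp window
    weight <- (windowWidth + config@fragmentLength) / 2000
    set.seed(config@seed + 77L)
    cts <- matrix(0L, length(win), nrow(libs),
                  dimnames = list(NULL, libs$name))
    bgPerWin <- config@backgroundRate * windowWidth / 1000
    for (j in seq_len(nrow(libs))) {
        set.seed(libs$substream[j] + 900000L)
        lfc <- if (mark != "h3k4me3") 0
               else switch(libs$condition[j],
                           TG = prom$lfcTG, nonTG = prom$lfcNonTG, 0)
        muProm <- .biasTransform(base * 2^lfc * libs$sizeFactor[j],
                                 libs$biasAmplitude[j],
                                 config@meanlogHigh,
                                 config@sdlogHigh * 1.5)
        muWin <- rep(muProm * weight, each = nWin) +
            bgPerWin * libs$sizeFactor[j]
        phi <- config@dispersion * if (libs$outlier[j]) 10 else 1
        cts[, j] <- rnbinom(length(muWin), mu = muWin, size = 1 / phi)
    }
    L <- seqlengths(config@genome)[[1]]
    totals <- colSums(cts) +
        round(config@backgroundRate * L / 1000 * libs$sizeFactor)
    WindowCounts(win, cts, totals = totals)
}

#' Write reads as a SAM file
#'
#' Emits an unsorted-header SAM with `@SQ` lines from the genome
#' declaration. Non-fragment records can be truncated to `readLength` from
#' their 5' end (reversing the fragment extension applied at counting
#' time); fragment records are written full-length.
#'
#' @param reads `GRanges` with `mapq` / `isDuplicate` metadata.
#' @param path output path.
#' @param genome `Seqinfo`.
#' @param readLength optional read length for 5'-truncation.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, path, genome, readLength = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:coordinate", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", seqnames(genome),
                       seqlengths(genome)), con)
    if (length(reads)) {
        gr <- reads
        if (!is.null(readLength)) {
            frag <- mcols(gr)$isFragment
            if (is.null(frag)) frag <- rep(FALSE, length(gr))
            gr[!frag] <- resize(gr[!frag], as.integer(readLength),
                                fix = "start")
        }
        gr <- sort(gr, ignore.strand = TRUE)
        dup <- mcols(gr)$isDuplicate
        if (is.null(dup)) dup <- rep(FALSE, length(gr))
        flag <- ifelse(as.character(strand(gr)) == "-", 16L, 0L) +
            ifelse(dup, 1024L, 0L)
        writeLines(sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                           seq_along(gr), flag,
                           as.character(seqnames(gr)), start(gr),
                           mcols(gr)$mapq, width(gr)), con)
    }
    invisible(path)
}

#' Write reads as a 6-column BED read table
#'
#' Columns: chrom, 0-based start, end, name, mapq, strand — the BED read
#' dialect [readAlignments()] accepts.
#'
#' @param reads `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReadsBed <- function(reads, path) {
    tab <- data.frame(chrom = as.character(seqnames(reads)),
                      start = start(reads) - 1L, end = end(reads),
                      name = sprintf("r%06d", seq_along(reads)),
                      mapq = mcols(reads)$mapq,
                      strand = ifelse(as.character(strand(reads)) == "-",
                                      "-", "+"))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Simulate a complete two-mark experiment
#'
#' Convenience wrapper: annotation + truth, H3K4me3 reads for all
#' libraries, H3K27me3 reads for all libraries.
#'
#' @param config a [simConfig()].
#' @param sequences forward to [simulateAnnotation()].
#' @return list with `genome`, `tss`, `sequences`, `truth`, `k4Reads`,
#'   `k27Reads`.
#' @export
simulateExperiment <- function(config = simConfig(), sequences = FALSE) {
    ann <- simulateAnnotation(config, sequences = sequences)
    k4 <- simulateReads(config, ann$truth, "h3k4me3")
    k27 <- simulateReads(config, ann$truth, "h3k27me3")
    c(ann, list(k4Reads = k4, k27Reads = k27))
}
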