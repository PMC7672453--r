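## Brute-force oracles, deliberately independent of the implementation
## paths they check (quadratic loops, explicit enumeration, closed forms).

## quadratic fragment x window overlap counter
bfCountOverlaps <- function(windows, frags) {
    out <- integer(length(windows))
    for (i in seq_along(windows)) {
        for (j in seq_along(frags)) {
            if (as.character(seqnames(windows))[i] ==
                as.character(seqnames(frags))[j] &&
                start(frags)[j] <= end(windows)[i] &&
                end(frags)[j] >= start(windows)[i])
                out[i] <- out[i] + 1L
        }
    }
    out
}

bfSimes <- function(p) {
    m <- length(p)
    ps <- sort(p)
    best <- Inf
    for (i in seq_len(m)) best <- min(best, m * ps[i] / i)
    min(1, best)
}

## step-up BH by hand
bfBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in rev(seq_len(m))) {
        val <- min(prev, m * p[o[i]] / i)
        adj[o[i]] <- val
        prev <- val
    }
    pmin(adj, 1)
}

## two-sided Fisher p by explicit enumeration over tables with fixed margins
bfFisherP <- function(a, b, cc, d) {
    r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
    kRange <- max(0, r1 + c1 - n):min(r1, c1)
    logp <- function(k) lchoose(c1, k) + lchoose(n - c1, r1 - k) -
        lchoose(n, r1)
    lp <- vapply(kRange, logp, 1)
    obs <- lp[kRange == a]
    sum(exp(lp[lp <= obs + 1e-7]))
}

## upper-tail hypergeometric from the combinatorial definition
bfHyperTail <- function(k, classSize, setSize, universeSize) {
    kk <- max(k, max(0, classSize - (universeSize - setSize))):
        min(classSize, setSize)
    if (k > min(classSize, setSize)) return(0)
    sum(exp(lchoose(setSize, kk) +
            lchoose(universeSize - setSize, classSize - kk) -
            lchoose(universeSize, classSize)))
}

## dinucleotide scan of a character sequence
bfCpgOE <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    keep <- ch %in% c("A", "C", "G", "T")
    L <- sum(keep)
    nC <- sum(ch == "C"); nG <- sum(ch == "G")
    nCG <- 0
    for (i in seq_len(length(ch) - 1))
        if (ch[i] == "C" && ch[i + 1] == "G") nCG <- nCG + 1
    if (nC * nG == 0) 0 else nCG * L / (nC * nG)
}

## independent merge/split: linear scan with the gap rule, then equal split
bfMergeSplit <- function(starts, ends, maxGap, maxWidth) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    cs <- starts[1]; ce <- ends[1]
    clusters <- list()
    for (i in seq_along(starts)[-1]) {
        gap <- starts[i] - ce - 1
        if (gap < maxGap) ce <- max(ce, ends[i])
        else { clusters[[length(clusters) + 1]] <- c(cs, ce)
               cs <- starts[i]; ce <- ends[i] }
    }
    clusters[[length(clusters) + 1]] <- c(cs, ce)
    out <- NULL
    for (cl in clusters) {
        span <- cl[2] - cl[1] + 1
        k <- ceiling(span / maxWidth)
        w <- rep(span %/% k, k)
        if (span %% k) w[seq_len(span %% k)] <- w[seq_len(span %% k)] + 1
        e <- cl[1] - 1 + cumsum(w)
        s <- c(cl[1], head(e, -1) + 1)
        out <- rbind(out, cbind(s, e))
    }
    out
}

## small simulated experiment shared by several tests
tinyConfig <- function(seed = 1, nPromoters = 250, genomeLength = 2e6,
                       nDifferential = 40, nDifferentialNonTG = 16, ...)
    simConfig(seed = seed, nPromoters = nPromoters,
              genomeLength = genomeLength,
              nDifferential = nDifferential,
              nDifferentialNonTG = nDifferentialNonTG, ...)

toyGenome <- function(len = 3000, name = "chrT")
    genomeDeclaration(name, len)

## window count container on a toy chromosome
makeWc <- function(cts, totals = colSums(cts) * 10) {
    cts <- as.matrix(cts)
    storage.mode(cts) <- "integer"
    w <- GRanges("chrT", IRanges(seq_len(nrow(cts)) * 200, width = 150))
    WindowCounts(w, cts, totals = totals)
}

## random single-end reads on a toy genome (already 'filtered': high mapq)
toyReads <- function(n, len = 3000, seed = 1, readLen = 50) {
    set.seed(seed)
    ## keep starts away from the ends so fragment extension never clips
    GRanges("chrT", IRanges(sample(148:(len - 147), n, replace = TRUE),
                            width = readLen),
            strand = sample(c("+", "-"), n, TRUE),
            mapq = 35L, isDuplicate = FALSE, isFragment = FALSE,
            seqinfo = toyGenome(len))
}
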