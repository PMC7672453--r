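test_that("fragment extension and window overlap counting match by hand", {
    genome <- toyGenome(600)
    grid <- windowGrid(genome, width = 150)
    ## 0-based position 100 -> 1-based 101; extended to [101, 247]
    read <- GRanges("chrT", IRanges(101, width = 50), strand = "+",
                    mapq = 35L, isDuplicate = FALSE, isFragment = FALSE,
                    seqinfo = genome)
    wc <- countWindows(read, grid, fragmentLength = 147)
    expect_equal(as.vector(counts(wc)), c(1L, 1L, 0L, 0L))
    expect_equal(libSizes(wc)[[1]], 1)
    ## minus-strand extension goes leftward
    readM <- GRanges("chrT", IRanges(401, width = 50), strand = "-",
                     mapq = 35L, isDuplicate = FALSE, isFragment = FALSE,
                     seqinfo = genome)
    wcM <- countWindows(readM, grid, fragmentLength = 147)
    ## fragment [304, 450] sits inside window 3 only
    expect_equal(as.vector(counts(wcM)), c(0L, 0L, 1L, 0L))
    ## zero reads -> all-zero counts
    wc0 <- countWindows(read[0], grid)
    expect_true(all(counts(wc0) == 0))
})

test_that("window counts equal the quadratic brute-force oracle", {
    genome <- toyGenome(3000)
    grid <- windowGrid(genome, width = 150)
    for (seed in 1:5) {
        reads <- toyReads(40, seed = seed)
        wc <- countWindows(reads, grid, fragmentLength = 147)
        frags <- GenomicRanges::resize(reads, 147, fix = "start")
        frags <- suppressWarnings(IRanges::trim(frags))
        expect_equal(as.vector(counts(wc)), bfCountOverlaps(grid, frags))
    }
})

test_that("background model follows the direct formula and CPM invariances", {
    genome <- toyGenome(4000)
    ## construct reads so the two 2000 bp bins hold 10 and 30 fragments
    pos <- c(seq(1, by = 10, length.out = 10),
             seq(2001, by = 10, length.out = 30))
    reads <- GRanges("chrT", IRanges(pos, width = 147), strand = "+",
                     mapq = 35L, isDuplicate = FALSE, isFragment = TRUE,
                     seqinfo = genome)
    bg <- backgroundModel(reads, genome, binWidth = 2000, windowWidth = 150)
    manual <- log2((c(10, 30) + 0.5) / (40 + 1) * 1e6) +
        log2(150 / 2000)
    expect_equal(sort(bg@binAbundance), sort(manual))
    expect_equal(globalBackground(bg), stats::median(manual))
    ## doubling all counts and totals leaves log2-CPM abundance unchanged
    ## (up to the 0.5 prior count, negligible at these depths)
    cts <- matrix(c(500L, 900L, 200L, 1000L), 2)
    w <- GRanges("chrT", IRanges(c(1, 151), width = 150))
    a1 <- abundance(WindowCounts(w, cts, totals = c(5000, 20000)))
    a2 <- abundance(WindowCounts(w, 2L * cts, totals = 2 * c(5000, 20000)))
    expect_equal(a1, a2, tolerance = 1e-3)
    ## uniform coverage: every scaled bin abundance equals the global level
    posU <- seq(1, 3800, by = 20)
    readsU <- GRanges("chrT", IRanges(posU, width = 100), strand = "+",
                      mapq = 35L, isDuplicate = FALSE, isFragment = TRUE,
                      seqinfo = genome)
    bgU <- backgroundModel(readsU, genome, binWidth = 2000)
    expect_lt(diff(range(bgU@binAbundance)), 0.1)
})

test_that("window filtering is strictly greater-than the threshold", {
    w <- GRanges("chrT", IRanges(c(1, 151, 301), width = 150))
    wc <- WindowCounts(w, matrix(c(0L, 10L, 1000L), 3), totals = 2000)
    bg <- abundance(wc)[2]
    expect_equal(filterWindows(wc, bg, minLog2FC = 5),
                 abundance(wc) - bg > 5)
    ## exactly at the threshold is not kept
    expect_false(filterWindows(wc, abundance(wc)[3] - 5, minLog2FC = 5)[3])
    expect_true(filterWindows(wc, abundance(wc)[3] - 5.1, minLog2FC = 5)[3])
    expect_error(filterWindows(wc, bg, minLog2FC = -1), ">= 0")
})

test_that("merging honours the gap rule and splits over-wide clusters", {
    ## gap 100 < 200: one region spanning both windows
    w <- GRanges("chrT", IRanges(c(1, 251), c(150, 400)))
    r <- mergeWindows(w, maxGap = 200, maxWidth = 7000)
    expect_length(r, 1)
    expect_equal(c(start(r), end(r)), c(1, 400))
    ## gap exactly 200 does not merge (strict 'less than maxGap apart')
    w2 <- GRanges("chrT", IRanges(c(1, 351), c(150, 500)))
    expect_length(mergeWindows(w2, maxGap = 200), 2)
    ## single window maps to itself
    r1 <- mergeWindows(w[1], maxGap = 200)
    expect_equal(c(start(r1), end(r1)), c(1, 150))
    ## a cluster spanning exactly 14 kb splits into two regions <= 7000 bp
    big <- GRanges("chrT", IRanges(c(seq(1, 13801, by = 150), 13851),
                                   width = 150))
    rs <- mergeWindows(big, maxGap = 200, maxWidth = 7000)
    expect_length(rs, 2)
    expect_true(all(width(rs) <= 7000))
    expect_equal(min(start(rs)), 1)
    expect_equal(max(end(rs)), 14000)
    expect_equal(sum(mcols(rs)$n_windows), length(big))
    ## unsorted input is refused
    expect_error(mergeWindows(rev(w), maxGap = 200), "sorted")
})

test_that("merge/split agrees with an independent scan-line oracle", {
    set.seed(99)
    for (case in 1:60) {
        n <- sample(2:25, 1)
        starts <- sort(sample(seq(1, 30000, by = 150), n))
        w <- GRanges("chrT", IRanges(starts, width = 150))
        maxGap <- sample(c(100, 200, 400), 1)
        maxWidth <- sample(c(2000, 7000), 1)
        r <- mergeWindows(w, maxGap = maxGap, maxWidth = maxWidth)
        o <- bfMergeSplit(starts, starts + 149, maxGap, maxWidth)
        expect_equal(start(r), unname(o[, 1]))
        expect_equal(end(r), unname(o[, 2]))
    }
})

test_that("region calling is idempotent and respects the blacklist", {
    set.seed(7)
    starts <- sort(sample(seq(1, 40000, by = 150), 40))
    w <- GRanges("chrT", IRanges(starts, width = 150))
    r1 <- mergeWindows(w, maxGap = 200, maxWidth = 7000)
    r2 <- mergeWindows(granges(r1), maxGap = 200, maxWidth = 7000)
    expect_equal(granges(r1), granges(r2))
    ## blacklisted windows are absent from the grid and from regions
    genome <- toyGenome(3000)
    bl <- GRanges("chrT", IRanges(1000, 1400))
    grid <- windowGrid(genome, width = 150, blacklist = bl)
    expect_false(any(IRanges::overlapsAny(grid, bl)))
    reads <- toyReads(200, seed = 3)
    prof <- markProfile("h3k4me3"); prof$minLog2FC <- 0
    called <- callRegions(reads, genome, profile = prof, blacklist = bl)
    if (length(called$regions))
        expect_false(any(IRanges::overlapsAny(called$regions, bl)))
})

test_that("planted enriched promoters are recovered as regions", {
    cfg <- tinyConfig(seed = 21)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    k4 <- simulateReads(cfg, ann$truth, "h3k4me3")
    rc <- callRegions(k4, ann$genome)
    tr <- ann$truth@promoters
    prom <- promoterRanges(ann$tss[tr$k4])
    hitRate <- mean(IRanges::overlapsAny(prom, rc$regions))
    expect_gte(hitRate, 0.95)
    ## every region holds at least one kept window
    expect_true(all(mcols(rc$regions)$n_windows >= 1))
})
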