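test_that("simulated annotation is deterministic with spaced unique TSSs", {
    cfg <- simConfig(seed = 3, nPromoters = 10, genomeLength = 2e5,
                     nDifferential = 2, nDifferentialNonTG = 1)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    expect_length(ann$tss, 10)
    expect_equal(anyDuplicated(ann$tss$gene_id), 0)
    expect_true(all(diff(start(ann$tss)) >= 5000))
    ann2 <- simulateAnnotation(cfg, sequences = FALSE)
    expect_identical(as.data.frame(ann$tss), as.data.frame(ann2$tss))
    expect_identical(as.data.frame(ann$truth@promoters),
                     as.data.frame(ann2$truth@promoters))
    ## a different seed moves the TSSs
    ann3 <- simulateAnnotation(simConfig(seed = 4, nPromoters = 10,
                                         genomeLength = 2e5,
                                         nDifferential = 2,
                                         nDifferentialNonTG = 1),
                               sequences = FALSE)
    expect_false(identical(start(ann$tss), start(ann3$tss)))
    ## infeasible spacing is refused
    expect_error(simulateAnnotation(simConfig(nPromoters = 100,
                                              genomeLength = 3e5,
                                              nDifferential = 10,
                                              nDifferentialNonTG = 5)),
                 "5 kb")
})

test_that("planted architecture respects the configured fractions", {
    cfg <- tinyConfig(seed = 8)
    tr <- simulateAnnotation(cfg, sequences = FALSE)$truth@promoters
    n <- length(tr)
    expect_equal(sum(tr$bivalent), round(0.15 * n))
    expect_equal(sum(tr$k4), round(0.55 * n))
    expect_equal(sum(tr$k27), round(0.25 * n))
    expect_true(all(tr$k4[tr$bivalent] & tr$k27[tr$bivalent]))
    expect_equal(sum(tr$diffTG), 40)
    expect_equal(sum(tr$diffNonTG), 16)
    ## differential promoters are K4-enriched with effects in [1,3]
    expect_true(all(tr$k4[tr$diffTG]))
    expect_true(all(abs(tr$lfcTG[tr$diffTG]) >= 1 &
                    abs(tr$lfcTG[tr$diffTG]) <= 3))
    expect_equal(tr$lfcTG[!tr$diffTG], rep(0, n - 40))
    ## the nonTG set overlaps the TG set at the configured fraction
    expect_equal(sum(tr$diffTG & tr$diffNonTG), round(0.75 * 16))
})

test_that("read simulation is seed-stable and respects degenerate configs", {
    cfg <- tinyConfig(seed = 14)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    r1 <- simulateReads(cfg, ann$truth, "h3k4me3")
    r2 <- simulateReads(cfg, ann$truth, "h3k4me3")
    expect_identical(lapply(r1, as.data.frame), lapply(r2, as.data.frame))
    ## no signal, no background: zero reads
    cfg0 <- tinyConfig(seed = 14, fracK4 = 0, fracK27 = 0,
                       fracBivalent = 0, nDifferential = 0,
                       nDifferentialNonTG = 0, backgroundRate = 0,
                       meanlogLow = -30)
    ann0 <- simulateAnnotation(cfg0, sequences = FALSE)
    r0 <- simulateReads(cfg0, ann0$truth, "h3k4me3")
    expect_true(all(vapply(r0, length, 1L) == 0))
    ## about 2% of reads sit at or below the MAPQ-20 filter
    mq <- unlist(lapply(r1, function(g) mcols(g)$mapq))
    expect_lt(abs(mean(mq <= 20) - 0.02), 0.01)
    ## h3k27me3 reads are fragment-style (no extension needed)
    r27 <- simulateReads(cfg, ann$truth, "h3k27me3")
    expect_true(all(mcols(r27[[1]])$isFragment))
})

test_that("realized counts carry the configured NB dispersion", {
    ## neutral size factors and bias so replicates are iid NB
    cfg <- simConfig(seed = 23, nPromoters = 600, genomeLength = 4e6,
                     nDifferential = 0, nDifferentialNonTG = 0,
                     libSizeFactorRange = c(1, 1), biasAmplitude = 0,
                     backgroundRate = 0, dispersion = 0.05)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    reads <- simulateReads(cfg, ann$truth, "h3k4me3")
    ctrl <- reads[grep("^CRwt", names(reads))]
    prom <- promoterRanges(ann$tss)
    cts <- vapply(ctrl, function(r)
        countOverlaps(prom, r, ignore.strand = TRUE),
        integer(length(prom)))
    keep <- ann$truth@promoters$k4
    m <- rowMeans(cts[keep, ]); v <- apply(cts[keep, ], 1, var)
    ## var = mu + phi mu^2: regress excess variance on mu^2 through origin
    phiHat <- sum((v - m) * m^2) / sum(m^4)
    expect_lt(abs(phiHat - 0.05) / 0.05, 0.2)
})

test_that("matrix-level window counts mirror the read-level generator", {
    cfg <- tinyConfig(seed = 9)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    wc <- simulateWindowCounts(cfg, ann$truth)
    expect_s4_class(wc, "WindowCounts")
    expect_equal(ncol(wc), 9)
    expect_equal(nrow(wc), 250 * 13)
    ## deterministic under the seed
    wc2 <- simulateWindowCounts(cfg, ann$truth)
    expect_identical(counts(wc), counts(wc2))
    ## enriched promoters dominate the count mass
    tr <- ann$truth@promoters
    byProm <- rowsum(rowMeans(counts(wc)), rowData(wc)$gene_id)
    enriched <- rownames(byProm) %in% tr$gene_id[tr$k4]
    expect_gt(median(byProm[enriched, 1]), 10 * median(byProm[!enriched, 1]))
})

test_that("SAM export of simulated reads round-trips through the reader", {
    cfg <- tinyConfig(seed = 17, backgroundRate = 0.01)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    reads <- simulateReads(cfg, ann$truth, "h3k4me3")[["CRwt_A"]]
    sam <- tempfile(fileext = ".sam")
    writeSam(reads, sam, ann$genome, readLength = 100)
    back <- readAlignments(sam, minMapq = 20, genome = ann$genome)
    kept <- sort(reads[mcols(reads)$mapq > 20], ignore.strand = TRUE)
    expect_equal(length(back), length(kept))
    ## 100 bp reads extend back to the original 147 bp fragments
    ext <- winchip:::.toFragments(back, 147)
    expect_equal(sort(start(ext)), sort(start(kept)))
    ## BED export round-trips likewise
    bed <- tempfile(fileext = ".bed")
    writeReadsBed(reads, bed)
    backBed <- readAlignments(bed, minMapq = 20, genome = ann$genome)
    expect_equal(length(backBed), length(kept))
    expect_equal(start(backBed), start(kept))
})
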