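test_that("MA values follow the geometric-mean reference formula", {
    cts <- matrix(c(10L, 40L, 160L, 10L, 40L, 160L), 3)
    wc <- makeWc(cts, totals = c(1000, 1000))
    ma <- maValues(wc, 1)
    expect_equal(ma$M, rep(0, 3))                 # identical libraries
    ## direct formula on a 3-window toy
    cts2 <- matrix(c(10L, 40L, 160L, 20L, 30L, 90L), 3)
    wc2 <- makeWc(cts2, totals = c(500, 500))
    l <- log2(sweep(cts2 + 0.5, 2, 501, "/") * 1e6)
    expect_equal(maValues(wc2, 2)$M, l[, 2] - rowMeans(l))
    expect_equal(maValues(wc2, 2)$A, rowMeans(l))
    ## doubling one library shifts its M by ~+1 uniformly
    cts3 <- cbind(cts[, 1], 2L * cts[, 1])
    wc3 <- makeWc(cts3, totals = c(1000, 1000))
    expect_equal(maValues(wc3, 2)$M - maValues(wc3, 1)$M,
                 rep(1, 3), tolerance = 0.05)
})

test_that("loess offsets recover planted biases and flatten trends", {
    ## two identical libraries: offsets are exactly zero after centering
    set.seed(1)
    y <- matrix(rpois(2000, 50), ncol = 2)
    storage.mode(y) <- "integer"
    wc <- makeWc(y, totals = c(5e4, 5e4))
    off0 <- loessNormalize(makeWc(cbind(y[, 1], y[, 1])))
    expect_true(all(abs(off0) < 1e-10))
    ## constant (linear in A with slope 0) bias of 0.5 log2 units
    y2 <- cbind(y[, 1], as.integer(round(y[, 1] * 2^0.5)))
    wcB <- makeWc(y2, totals = c(5e4, 5e4))
    offB <- loessNormalize(wcB)
    rec <- offB[, 2] - offB[, 1]
    inner <- abundance(wcB) > quantile(abundance(wcB), 0.1) &
        abundance(wcB) < quantile(abundance(wcB), 0.9)
    expect_lt(median(abs(rec[inner] - 0.5)), 0.05)
    ## planted smooth monotone bias, no differential: post-offset residual
    ## M-trend under 0.1 in every abundance decile (seeded generator)
    cfg <- tinyConfig(seed = 5, nDifferential = 0, nDifferentialNonTG = 0)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    wcS <- simulateWindowCounts(cfg, ann$truth)
    keep <- rowData(wcS)$gene_id %in%
        ann$truth@promoters$gene_id[ann$truth@promoters$k4]
    wcK <- wcS[keep, ]
    off <- loessNormalize(wcK)
    l <- log2(sweep(counts(wcK) + 0.5, 2, libSizes(wcK) + 1, "/") * 1e6)
    Mres <- (l - off) - rowMeans(l - off)
    A <- rowMeans(l)
    dec <- cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE)
    for (j in seq_len(ncol(l))) {
        trend <- tapply(Mres[, j], dec, mean)
        expect_lt(max(abs(trend)), 0.1)
    }
    ## too few windows to fit a trend is a helpful error
    expect_error(loessNormalize(makeWc(y[1:3, , drop = FALSE])), "windows")
})

test_that("MDS distances match the brute-force top-k RMS oracle", {
    set.seed(42)
    y <- matrix(rnbinom(800 * 4, mu = 60, size = 10), 800)
    wc <- makeWc(y, totals = rep(6e4, 4))
    q <- mdsQC(wc, 0, topK = 100)
    l <- log2(sweep(y + 0.5, 2, libSizes(wc) + 1, "/") * 1e6)
    for (a in 1:3) for (b in (a + 1):4) {
        d2 <- sort((l[, a] - l[, b])^2, decreasing = TRUE)[1:100]
        expect_equal(q$distances[a, b], sqrt(mean(d2)), tolerance = 1e-10)
    }
    ## duplicated sample: distance zero, coincident coordinates
    y2 <- cbind(y, y[, 4])
    q2 <- mdsQC(makeWc(y2, totals = rep(6e4, 5)), 0, topK = 100)
    expect_equal(q2$distances[4, 5], 0)
    expect_equal(q2$coordinates[4, ], q2$coordinates[5, ],
                 tolerance = 1e-8)
    expect_error(mdsQC(makeWc(y[, 1:2]), 0), "3 samples")
})

test_that("the planted outlier replicate is flagged at c = 2", {
    cfg <- tinyConfig(seed = 31, outlierReplicate = TRUE,
                      nDifferential = 0, nDifferentialNonTG = 0)
    ann <- simulateAnnotation(cfg, sequences = FALSE)
    expect_true(any(ann$truth@libraries$outlier))
    wcS <- simulateWindowCounts(cfg, ann$truth)
    keep <- rowData(wcS)$gene_id %in%
        ann$truth@promoters$gene_id[ann$truth@promoters$k4]
    wcK <- wcS[keep, ]
    q <- mdsQC(wcK, loessNormalize(wcK), outlierC = 2)
    expect_true(q$outliers[["TG_A"]])
    expect_equal(sum(q$outliers), 1)
})

test_that("window tests recover planted effects and behave at degenerate input", {
    set.seed(8)
    nw <- 2000
    mu <- exp(runif(nw, log(20), log(120)))
    lfc <- rep(c(0, 2), c(1600, 400))
    y <- cbind(matrix(rnbinom(nw * 3, mu = mu, size = 20), nw),
               matrix(rnbinom(nw * 3, mu = mu * 2^lfc, size = 20), nw))
    storage.mode(y) <- "integer"
    y[1, ] <- 0L                                  # an all-zero window
    wc <- makeWc(y, totals = rep(sum(mu) * 1.2, 6))
    grp <- factor(rep(c("ctl", "trt"), each = 3), levels = c("ctl", "trt"))
    res <- testWindows(wc, 0, grp)
    expect_equal(mcols(res)$PValue[1], 1)
    expect_equal(mcols(res)$logFC[1], 0)
    expect_true(all(mcols(res)$PValue >= 0 & mcols(res)$PValue <= 1))
    ## median estimated log2FC of planted windows within +/- 0.25 of 2
    est <- mcols(res)$logFC[lfc == 2]
    expect_lt(abs(median(est) - 2), 0.25)
    ## planted windows overwhelmingly significant, nulls mostly not
    expect_gt(mean(mcols(res)$PValue[lfc == 2] < 0.01), 0.9)
    expect_lt(mean(mcols(res)$PValue[lfc == 0] < 0.01), 0.05)
    expect_error(testWindows(wc, 0, factor(rep("a", 6))), "two levels")
})

test_that("single-replicate groups warn and accept shared dispersions", {
    set.seed(9)
    y <- matrix(rnbinom(3000, mu = 50, size = 20), ncol = 3)
    storage.mode(y) <- "integer"
    wc <- makeWc(y, totals = rep(5e4, 3))
    grp <- factor(c("ctl", "ctl", "trt"), levels = c("ctl", "trt"))
    expect_warning(testWindows(wc, 0, grp), "single replicate")
    expect_silent(res <- testWindows(wc, 0, grp, dispersion = 0.05))
    expect_true(all(is.finite(mcols(res)$PValue)))
})

test_that("Simes combination matches its definition and brute force", {
    expect_equal(simesP(c(0.01, 0.02, 0.9)), 0.03)
    expect_equal(simesP(0.05), 0.05)
    expect_equal(simesP(rep(1, 5)), 1)
    set.seed(11)
    for (i in 1:1000) {
        p <- runif(sample(1:8, 1))
        expect_equal(simesP(p), bfSimes(p), tolerance = 1e-12)
    }
    ## bounds: min(p) <= simes <= m * min(p)
    for (i in 1:50) {
        p <- runif(sample(2:10, 1))
        s <- simesP(p)
        expect_gte(s, min(p) - 1e-12)
        expect_lte(s, length(p) * min(p) + 1e-12)
    }
})

test_that("promoter combination collects overlapping windows only", {
    tss <- tssAnnotation(c("gA", "gB", "gC"), "chrT",
                         c(1000, 6000, 11000))
    win <- GRanges("chrT", IRanges(c(200, 800, 1500, 5800, 20000),
                                   width = 150))
    mcols(win)$PValue <- c(0.01, 0.02, 0.9, 0.04, 0.5)
    mcols(win)$logFC <- c(1, 2, -1, -3, 1)
    mcols(win)$abundance <- rep(5, 5)
    pr <- simesCombine(win, tss, radius = 1000)
    expect_equal(pr$gene_id, c("gA", "gB"))       # gC has no window
    expect_equal(pr$n_windows, c(3L, 1L))
    expect_equal(pr$simes_p[1], bfSimes(c(0.01, 0.02, 0.9)))
    expect_equal(pr$simes_p[2], 0.04)
    expect_equal(pr$direction, c(1L, -1L))        # sign at smallest p
})

test_that("BH adjustment equals the hand step-up and is used for calls", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    set.seed(12)
    for (i in 1:1000) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhAdjust(p), bfBH(p), tolerance = 1e-12)
    }
    ## strict FDR threshold: 0.2 exactly is not differential
    pr <- S4Vectors::DataFrame(gene_id = c("a", "b", "c"),
                               simes_p = c(0.5, 0.2, 0.1),
                               fdr = c(0.3, 0.2, 0.199))
    called <- callDifferential(pr, alpha = 0.2)
    expect_equal(called$is_differential, c(FALSE, FALSE, TRUE))
    empty <- callDifferential(pr[0, ], alpha = 0.2)
    expect_equal(nrow(empty), 0)
})
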