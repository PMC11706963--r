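test_that("CpG reader destrands and applies the RRBS coverage filter", {
    df <- data.frame(chrom = "chr1", pos = c(100L, 101L, 300L),
                     strand = c("+", "-", "+"),
                     count_M = c(3L, 2L, 2L), count_U = c(1L, 0L, 2L),
                     sample_id = "s1")
    em <- readCpgCounts(df, dialect = "emseq")
    expect_equal(nrow(em), 2L)
    merged <- em[em$pos == 100L, ]
    expect_equal(merged$count_M, 5L)       # (3,1) + (2,0) on the same CpG
    expect_equal(merged$count_U, 1L)

    rr <- readCpgCounts(df, dialect = "rrbs")   # the 2+2=4-read CpG drops
    expect_equal(rr$pos, 100L)

    expect_error(readCpgCounts(transform(df, count_M = c(-1L, 2L, 2L))),
                 "negative")
    expect_error(readCpgCounts(transform(df, strand = c("+", "x", "+"))),
                 "strand")
})

test_that("tile aggregation sums member CpGs and conserves counts", {
    tiles <- makeGenomeTiles(c(chr1 = 1000))
    cpgs <- data.frame(chrom = "chr1", pos = c(10L, 20L, 700L),
                       count_M = c(3L, 5L, 4L), count_U = c(2L, 0L, 6L),
                       sample_id = "s1")
    tm <- aggregateToTiles(cpgs, tiles)
    expect_equal(unname(methCounts(tm)[, "s1"]), c(8, 4))
    expect_equal(unname(totalCounts(tm)[, "s1"]), c(10, 10))
    expect_equal(unname(percentMeth(tm)[, "s1"]), c(80, 40))
    # conservation over a random fixture
    set.seed(21)
    big <- data.frame(chrom = "chr1", pos = sample(0:999, 50),
                      count_M = rpois(50, 5), count_U = rpois(50, 5),
                      sample_id = sample(c("a", "b"), 50, replace = TRUE))
    tm2 <- aggregateToTiles(big, tiles)
    expect_equal(sum(methCounts(tm2)), sum(big$count_M))
    expect_equal(sum(totalCounts(tm2)), sum(big$count_M + big$count_U))
    # tile with no covered CpG reports missing percent
    none <- aggregateToTiles(cpgs[cpgs$pos < 500, ], tiles)
    expect_true(is.na(percentMeth(none)[2, "s1"]))
})

test_that("testing filter requires minimum CpGs and coverage in every sample", {
    m <- rbind(c(10, 10), c(10, 10), c(10, 10))
    t <- rbind(c(30, 30), c(25, 24), c(30, 30))
    tm <- make_tm(m, t, n_cpg = c(4L, 5L, 5L))
    colnames(t) <- colnames(m) <- NULL
    kept <- filterTiles(tm, minCpg = 5, minReads = 25)
    # tile 1 fails the CpG rule, tile 2 fails coverage in one sample
    expect_equal(S4Vectors::mcols(rowRanges(kept))$tile_id, "chrT:1000-1500")
})

test_that("differential methylation test matches a closed-form binomial LRT", {
    m <- rbind(c(50, 50, 50, 50),
               c(10, 12, 88, 90))
    t <- matrix(100, 2, 4, dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
    dimnames(m) <- dimnames(t)
    tm <- make_tm(m, t)
    res <- testDifferentialMethylation(tm, c("A1", "A2"), c("B1", "B2"),
                                       phi = 0)
    expect_equal(res$delta_me[1], 0)
    expect_gt(res$p_value[1], 0.9)
    expect_lt(res$p_value[2], 1e-6)
    expect_equal(res$delta_me[2], 100 * (178 / 200 - 22 / 200))
    # oracle agreement
    expect_equal(res$p_value[2],
                 binom_lrt_oracle(c(10, 12), c(100, 100),
                                  c(88, 90), c(100, 100)),
                 tolerance = 1e-8)
})

test_that("the test has power at a 30-point shift under overdispersion", {
    set.seed(77)
    n <- 200
    t <- matrix(rpois(n * 4, 300), n, 4,
                dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
    m <- t
    # per-CpG beta-binomial structure approximated at tile level: a tile of
    # 10 CpGs at depth 30 has effective overdispersion ~ phi*(30-1)/(300-1)
    phi_eff <- 0.02 * 29 / 299
    for (j in 1:2) m[, j] <- rbb(n, t[, j], 0.35, phi_eff)
    for (j in 3:4) m[, j] <- rbb(n, t[, j], 0.65, phi_eff)
    tm <- make_tm(m, t)
    res <- testDifferentialMethylation(tm, c("A1", "A2"), c("B1", "B2"))
    expect_gt(mean(res$p_value < 0.05), 0.9)
})

test_that("BH adjustment equals the step-up oracle and handles missing p", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(8)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bh_oracle(p), tolerance = 1e-12)
    }
    out <- bhAdjust(c(0.01, NA, 0.04))
    expect_true(is.na(out[2]))
    expect_equal(out[c(1, 3)], bh_oracle(c(0.01, 0.04)))
})

test_that("DMR calling applies sign and thresholds and is monotone", {
    rec <- data.frame(tile_id = c("a", "b", "c"),
                      delta_me = c(-30, 30, -10),
                      p_value = c(1e-4, 1e-4, 1e-5),
                      fdr = c(0.01, 0.01, 0.001))
    out <- callDmrs(rec, 25, 0.05)
    expect_equal(as.character(out$direction), c("hypo", "hyper", "none"))
    s <- attr(out, "summary")
    expect_equal(s$n_significant, 2L)

    empty <- callDmrs(rec[0, ], 25, 0.05)
    expect_equal(nrow(empty), 0L)

    set.seed(12)
    batch <- data.frame(tile_id = as.character(1:500),
                        delta_me = runif(500, -60, 60),
                        p_value = runif(500))
    batch$fdr <- bhAdjust(batch$p_value)
    loose <- callDmrs(batch, 25, 0.05)
    tight <- callDmrs(batch, 25, 0.01)
    expect_true(all(which(tight$direction != "none") %in%
                    which(loose$direction != "none")))
    tight_d <- callDmrs(batch, 40, 0.05)
    expect_true(all(which(tight_d$direction != "none") %in%
                    which(loose$direction != "none")))
})
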