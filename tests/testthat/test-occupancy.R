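test_that("log2 RPKM follows the pseudocount formula", {
    expect_equal(log2Rpkm(matrix(10), 1e6, 500), matrix(log2(21)))
    expect_equal(log2Rpkm(matrix(0), 1e6, 500), matrix(0))
    x <- matrix(rpois(20, 50), 10, 2)
    expect_equal(log2Rpkm(x, c(1e6, 1e6), 500) -
                 log2Rpkm(x, c(2e6, 2e6), 500),
                 matrix(1, 10, 2))
    expect_error(log2Rpkm(matrix(1), 0, 500), "library size")
    # round trip back to counts
    expect_equal(rpkmToCounts(log2Rpkm(x, c(1e6, 2e6)), c(1e6, 2e6)), x)
})

test_that("cyclic loess leaves identical samples untouched and keeps means", {
    set.seed(41)
    x <- matrix(rnorm(500, 7, 1), 500, 1)[, c(1, 1, 1)]
    norm <- cyclicLoessNormalize(x)
    expect_equal(unclass(norm)[, ], x[, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
    y <- x + matrix(rnorm(1500, 0, 0.3), 500, 3)
    ny <- cyclicLoessNormalize(y)
    expect_lt(max(abs(rowMeans(ny) - rowMeans(y))), 1e-6)
    expect_error(cyclicLoessNormalize(y[1:10, ]), "too few tiles")
})

test_that("cyclic loess removes constant offsets and smooth biases", {
    set.seed(42)
    n <- 10000
    base <- rnorm(n, 7, 1)
    x <- sapply(1:3, function(i) base + rnorm(n, 0, 0.3))
    x[, 2] <- x[, 2] + 1                       # constant offset
    nx <- cyclicLoessNormalize(x)
    off <- mean(nx[, 2] - (nx[, 1] + nx[, 3]) / 2)
    expect_lt(abs(off), 0.05)

    b <- 0.5 * sin(base)                       # smooth intensity bias
    y <- sapply(1:3, function(i) base + rnorm(n, 0, 0.3))
    y[, 1] <- y[, 1] + b
    ny <- cyclicLoessNormalize(y)
    resid <- (ny[, 1] - (ny[, 2] + ny[, 3]) / 2)
    dec <- cut(base, quantile(base, 0:10 / 10), include.lowest = TRUE)
    expect_lt(max(abs(tapply(resid, dec, mean))), 0.1)
})

test_that("fast cyclic loess agrees with the reference implementation", {
    skip_if_not_installed("limma")
    set.seed(43)
    n <- 4000
    x <- sapply(1:4, function(i) rnorm(n, 7, 1))
    x[, 1] <- x[, 1] + 0.4
    ours <- cyclicLoessNormalize(x, trim = FALSE)
    ref <- limma::normalizeCyclicLoess(x, span = 0.7, iterations = 1,
                                       method = "fast")
    # same up to the mean-preserving centring (a per-tile constant):
    # compare all between-sample differences
    for (j in 2:4)
        expect_lt(max(abs((ours[, j] - ours[, 1]) - (ref[, j] - ref[, 1]))),
                  1e-8)
})

test_that("common NB dispersion is recovered from simulated counts", {
    set.seed(44)
    n <- 5000
    mu <- 2^rnorm(n, 6.6, 0.6)
    cnt <- matrix(rnbinom(n * 4, mu = rep(mu, 4), size = 10), n, 4)
    d <- methTiles:::estimateCommonDispersion(cnt, c("A", "A", "B", "B"))
    expect_gt(d, 0.07); expect_lt(d, 0.13)
})

test_that("NB LRT matches a glm-based fit and is calibrated on nulls", {
    set.seed(45)
    n <- 200
    cnt <- matrix(rnbinom(n * 4, mu = rep(2^rnorm(n, 6, 1), 4), size = 8),
                  n, 4)
    off <- log(c(9e5, 1.1e6, 1.2e6, 8e5))
    p1 <- methTiles:::nb_lrt_two_group(cnt, c("A", "A", "B", "B"), off, 0.125)
    fam <- MASS::negative.binomial(theta = 8)
    X1 <- stats::model.matrix(~0 + factor(c("A", "A", "B", "B")))
    X0 <- matrix(1, 4, 1)
    p2 <- vapply(seq_len(n), function(i) {
        f1 <- stats::glm.fit(X1, cnt[i, ], family = fam, offset = off)
        f0 <- stats::glm.fit(X0, cnt[i, ], family = fam, offset = off)
        pchisq(max(0, f0$deviance - f1$deviance), 1, lower.tail = FALSE)
    }, numeric(1))
    expect_lt(max(abs(p1 - p2)), 1e-6)

    set.seed(46)
    n <- 5000
    cnt <- matrix(rnbinom(n * 4, mu = rep(2^rnorm(n, 6.6, 0.6), 4),
                          size = 10), n, 4)
    lr <- log2Rpkm(cnt, rep(1e6, 4), 500)
    res <- testDifferentialOccupancy(lr[, 1:2], lr[, 3:4],
                                     rep(1e6, 2), rep(1e6, 2))
    rate <- mean(res$p_value < 0.05)
    expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("differential occupancy recovers a planted four-fold change", {
    set.seed(47)
    n <- 3000
    a <- matrix(rnbinom(n * 2, mu = 100, size = 10), n, 2)
    b <- matrix(rnbinom(n * 2, mu = 400, size = 10), n, 2)
    lrA <- log2Rpkm(a, rep(1e6, 2), 500); lrB <- log2Rpkm(b, rep(1e6, 2), 500)
    res <- testDifferentialOccupancy(lrA, lrB, rep(1e6, 2), rep(1e6, 2))
    expect_lt(abs(median(res$log2fc) - 2), 0.15)
    # group swap flips the sign
    swap <- testDifferentialOccupancy(lrB, lrA, rep(1e6, 2), rep(1e6, 2))
    expect_equal(swap$log2fc, -res$log2fc, tolerance = 1e-12)
    # equal group means give zero fold change
    same <- testDifferentialOccupancy(lrA, lrA, rep(1e6, 2), rep(1e6, 2))
    expect_equal(same$log2fc, rep(0, n))
})

test_that("fold-change trichotomy uses strict boundaries", {
    expect_equal(as.character(trichotomizeLfc(c(0.6, -0.6, 0.5, -0.5, 0))),
                 c("increased", "reduced", "unaltered", "unaltered",
                   "unaltered"))
    x <- rnorm(50)
    expect_equal(as.character(trichotomizeLfc(-x)),
                 as.character(factor(trichotomizeLfc(x),
                                     levels = c("reduced", "unaltered",
                                                "increased"),
                                     labels = c("increased", "unaltered",
                                                "reduced"))))
})

test_that("peak filtering drops weak and outlier-length peaks", {
    set.seed(48)
    pk <- data.frame(chrom = "chr1", start = 0:99 * 1000,
                     end = 0:99 * 1000 + c(rep(300, 99), 10000),
                     q_value = 1e-5)
    out <- filterPeaks(pk, genomeSize = 1e6)
    expect_equal(out$summary$n_peaks, 99L)
    expect_equal(out$summary$median_length, 300)
    expect_equal(out$summary$fraction_genome_covered, 99 * 300 / 1e6)

    allweak <- filterPeaks(transform(pk, q_value = 0.5))
    expect_equal(allweak$summary$n_peaks, 0L)

    med <- data.frame(chrom = "c", start = c(0, 0, 0),
                      end = c(100, 200, 300), q_value = 0)
    expect_equal(median(med$end - med$start), 200)

    empty <- filterPeaks(pk[0, ])
    expect_equal(empty$summary$n_peaks, 0L)
    expect_equal(empty$summary$fraction_genome_covered, 0)
})
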