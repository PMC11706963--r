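test_that("natural spline basis has df columns and reproduces lines", {
    set.seed(81)
    x <- runif(14)
    b <- naturalSplineBasis(x, df = 3)
    expect_equal(ncol(b), 3L)
    fit <- lm(x ~ b)
    expect_lt(max(abs(residuals(fit))), 1e-8)
    # second differences vanish beyond the boundary knots (linearity)
    grid <- seq(min(x) - 2, min(x) - 0.5, length.out = 50)
    bb <- predict(b, grid)
    d2 <- diff(bb, differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
    expect_error(naturalSplineBasis(rep(0.5, 10), df = 3), "distinct")
})

test_that("two-group DE excludes low-CPM genes and finds strong effects", {
    set.seed(82)
    n <- 300
    mu <- 2^runif(n, 5, 9)
    lfc <- rep(0, n); lfc[1:30] <- 2 * sample(c(-1, 1), 30, replace = TRUE)
    cnt <- cbind(matrix(rnbinom(n * 3, mu = rep(mu, 3), size = 10), n, 3),
                 matrix(rnbinom(n * 3, mu = rep(mu * 2^lfc, 3), size = 10),
                        n, 3))
    rownames(cnt) <- paste0("g", seq_len(n))
    low <- matrix(0L, 1, 6, dimnames = list("lowgene", NULL))
    low[] <- 0L   # CPM 0 everywhere: always filtered
    res <- deTwoGroup(rbind(cnt, low), rep(c("a", "b"), each = 3),
                      librarySize = rep(1e6, 6))
    expect_false("lowgene" %in% res$id)
    hit <- res[match(paste0("g", 1:30), res$id), ]
    expect_gte(mean(sign(hit$log2fc) == sign(lfc[1:30])), 0.99)
    expect_gt(mean(hit$significant), 0.9)
})

test_that("a gene below the CPM threshold in all samples is excluded", {
    cnt <- rbind(high = rep(1000L, 6), low = rep(0L, 6))
    # give 'low' CPM 0.5 at a 2e6 library: 1 read
    cnt["low", ] <- 1L
    res <- deTwoGroup(cnt, rep(c("a", "b"), each = 3),
                      librarySize = rep(2e6, 6))
    expect_equal(res$id, "high")
})

test_that("pseudotime adjustment requires an identifiable design", {
    cnt <- matrix(rpois(10 * 8, 50), 10, 8)
    expect_error(dePseudotimeAdjusted(cnt, rep(c("a", "b"), each = 4),
                                      rep(0.5, 8)),
                 "non-identifiable|distinct")
})

test_that("the spline model absorbs a shared trend and keeps genotype power", {
    cfg <- simulationConfig(seed = 83,
                            expression = list(nGenes = 600L))
    sim <- simulateExpression(cfg)
    adj <- dePseudotimeAdjusted(sim$counts, sim$genotype, sim$pst,
                                sim$librarySize)
    tr <- sim$truth[match(adj$id, sim$truth$gene), ]
    null <- tr$log2fc == 0
    expect_lt(mean(adj$p[null] < 0.05), 0.09)
    expect_gte(mean(adj$significant[!null]), 0.8)
    # the naive two-group test is fooled by the developmental delay
    two <- deTwoGroup(sim$counts, sim$genotype, sim$librarySize)
    tr2 <- sim$truth[match(two$id, sim$truth$gene), ]
    trend_only <- tr2$log2fc == 0 & abs(tr2$trend_beta) > 0.5
    expect_gt(mean(two$p[trend_only] < 0.05),
              2 * mean(adj$p[null] < 0.05))
})

test_that("permuted-pseudotime control is reproducible and validated", {
    cfg <- simulationConfig(seed = 84,
                            expression = list(nGenes = 150L,
                                              effectFraction = 0))
    sim <- simulateExpression(cfg)
    pc1 <- permutationControl(sim$counts, sim$genotype, sim$pst,
                              nPerm = 2, seed = 99,
                              librarySize = sim$librarySize)
    pc2 <- permutationControl(sim$counts, sim$genotype, sim$pst,
                              nPerm = 2, seed = 99,
                              librarySize = sim$librarySize)
    expect_identical(pc1, pc2)
    expect_length(pc1$permuted, 2L)
    expect_error(permutationControl(sim$counts, sim$genotype, sim$pst,
                                    nPerm = 0, seed = 1), "nPerm")
})

test_that("expression strata are quartile bins with ties going down", {
    expect_equal(stratifyByExpression(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
    expect_warning(s <- stratifyByExpression(rep(3, 5)), "constant")
    expect_equal(s, rep(1L, 5))
    set.seed(85)
    x <- rnorm(100)
    expect_equal(stratifyByExpression(x), stratifyByExpression(exp(x)))
    expect_equal(stratifyByExpression(x), stratifyByExpression(2 * x + 7))
})
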