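test_that("every generator is a deterministic function of the seed", {
    c1 <- simulationConfig(seed = 91, nTilesPerGroup = 5L, nNullTiles = 20L,
                           occupancy = list(nTiles = 200L, nPlanted = 10L),
                           allelic = list(nReads = 200L),
                           expression = list(nGenes = 50L))
    c2 <- simulationConfig(seed = 92, nTilesPerGroup = 5L, nNullTiles = 20L,
                           occupancy = list(nTiles = 200L, nPlanted = 10L),
                           allelic = list(nReads = 200L),
                           expression = list(nGenes = 50L))
    expect_identical(simulateMethylome(c1), simulateMethylome(c1))
    expect_identical(simulateOccupancy(c1, bias = TRUE),
                     simulateOccupancy(c1, bias = TRUE))
    expect_identical(simulateAllelicReads(c1), simulateAllelicReads(c1))
    expect_identical(simulateExpression(c1), simulateExpression(c1))
    expect_false(identical(simulateMethylome(c1)$cpgs,
                           simulateMethylome(c2)$cpgs))
    expect_error(simulationConfig(), "seed")
})

test_that("methylome truth lies inside the group boxes and matches labels", {
    sim <- simulateMethylome(simulationConfig(seed = 93,
                                              nTilesPerGroup = 50L,
                                              nNullTiles = 100L))
    tr <- sim$truth
    planted <- tr$group != "null"
    # noise-free classification of the truth recovers every label
    cls <- classifyHypoDmr(tr$psg[planted], tr$ctrl[planted],
                           tr$dko[planted], tr$gc_percent[planted])
    expect_equal(as.character(cls), tr$group[planted])
    # every planted tile is a genuine hypoDMR by the stated threshold
    expect_true(all(tr$delta[planted] < -25))
    # nulls are constant across conditions
    expect_true(all(tr$delta[!planted] == 0))
    # GC class parity: odd groups GC-rich, even GC-poor
    odd <- tr$group %in% c("1", "3", "5")
    even <- tr$group %in% c("2", "4", "6")
    expect_true(all(tr$gc_percent[odd] > 50))
    expect_true(all(tr$gc_percent[even] < 50))
})

test_that("high-coverage zero-dispersion methylomes converge to the truth", {
    cfg <- simulationConfig(seed = 94, nTilesPerGroup = 10L,
                            nNullTiles = 30L, coverage = 10000, phi = 0)
    sim <- simulateMethylome(cfg)
    tm <- aggregateToTiles(sim$cpgs, sim$tiles)
    ctrl <- sim$samples$sample_id[sim$samples$condition == "ctrl"]
    est <- percentMeth(tm[, ctrl], pooled = TRUE)
    expect_lt(max(abs(est - sim$truth$ctrl)), 1)
})

test_that("generated counts match their analytic moments", {
    set.seed(95)
    # beta-binomial moments through the methylome generator at one tile
    cfg <- simulationConfig(seed = 95, nTilesPerGroup = 0L,
                            nNullTiles = 2000L, coverage = 40, phi = 0.1)
    sim <- simulateMethylome(cfg)
    tm <- aggregateToTiles(sim$cpgs, sim$tiles)
    # occupancy NB: mean and variance of null tiles
    oc <- simulateOccupancy(simulationConfig(
        seed = 96, occupancy = list(nTiles = 20000L, nPlanted = 0L,
                                    sdLog2 = 0, dispersion = 0.1)))
    x <- as.vector(oc$counts)
    mu <- 2^log2(100)
    se_var <- sqrt(2 / length(x)) * (mu + 0.1 * mu^2)  # rough 3-SE guard
    expect_lt(abs(mean(x) - mu), 3 * sqrt((mu + 0.1 * mu^2) / length(x)))
    expect_lt(abs(var(x) - (mu + 0.1 * mu^2)), 3 * se_var)
})

test_that("planted occupancy effects and bias behave as configured", {
    cfg <- simulationConfig(seed = 97,
                            occupancy = list(nTiles = 1000L, nPlanted = 50L))
    sim <- simulateOccupancy(cfg)
    expect_equal(sum(sim$truth$log2fc != 0), 50L)
    expect_true(all(abs(sim$truth$log2fc[sim$truth$log2fc != 0]) == 2))
    # the bias distorts counts but never the planted truth
    simb <- simulateOccupancy(cfg, bias = TRUE)
    expect_false(identical(sim$counts[, 1], simb$counts[, 1]))
    expect_identical(sim$truth, simb$truth)
})
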