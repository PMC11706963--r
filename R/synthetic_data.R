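#' Simulation configuration
#'
#' Bundles the parameters of the four seeded generators.  Defaults emulate
#' the study conditions of the germline methylome experiments: two
#' replicates per condition, ~30x per-CpG coverage, mild beta-binomial
#' overdispersion, 200 planted hypoDMR tiles per trajectory group over 5000
#' null tiles; negative-binomial occupancy counts with a strong
#' intensity-dependent efficiency bias available for normalization tests;
#' a hybrid cross with ~1 SNP per 200 bp; and embryo expression counts with
#' a smooth pseudotime trend confounded with genotype.
#'
#' @param seed RNG seed (mandatory).
#' @param nTilesPerGroup planted hypoDMR tiles per group 1..6 (default 200).
#' @param nNullTiles unchanged tiles (default 5000).
#' @param coverage mean reads per CpG per sample (default 30).
#' @param phi per-CpG beta-binomial overdispersion (default 0.02).
#' @param replicates replicates per condition (default 2).
#' @param occupancy list: \code{nTiles, meanLog2, sdLog2, dispersion,
#'   nPlanted, plantedLfc, biasAmplitude, replicates}.
#' @param allelic list: \code{chromLength, snpPer100bp, readLength,
#'   errorRate, nReads}.
#' @param expression list: \code{nGenes, nPerGenotype, baseMeanLog2,
#'   dispersion, trendSd, curveSd, effectFraction, effectLfc, delay}.
#' @return a list of class \code{"methTilesSimConfig"}.
#' @export
simulationConfig <- function(seed,
                             nTilesPerGroup = 200L,
                             nNullTiles = 5000L,
                             coverage = 30,
                             phi = 0.02,
                             replicates = 2L,
                             occupancy = list(),
                             allelic = list(),
                             expression = list()) {
    if (missing(seed)) stop("seed is mandatory")
    occ <- utils::modifyList(list(nTiles = 5000L, meanLog2 = log2(100),
                                  sdLog2 = 0.6, dispersion = 0.1,
                                  nPlanted = 100L, plantedLfc = 2,
                                  biasAmplitude = 0.75, replicates = 2L),
                             occupancy)
    al <- utils::modifyList(list(chromLength = 100000L, snpPer100bp = 0.5,
                                 readLength = 100L, errorRate = 0,
                                 nReads = 20000L),
                            allelic)
    ex <- utils::modifyList(list(nGenes = 2000L, nPerGenotype = 7L,
                                 baseMeanLog2 = log2(200), baseSdLog2 = 1,
                                 dispersion = 0.1, trendSd = 1,
                                 curveSd = 0.5, effectFraction = 0.05,
                                 effectLfc = 2, delay = 0.3),
                            expression)
    structure(list(seed = as.integer(seed),
                   nTilesPerGroup = nTilesPerGroup,
                   nNullTiles = nNullTiles, coverage = coverage, phi = phi,
                   replicates = replicates, occupancy = occ, allelic = al,
                   expression = ex),
              class = "methTilesSimConfig")
}

## truth-sampling boxes: strictly interior to the classification boxes so
## that binomial sampling noise at ~30x coverage rarely crosses a decision
## boundary, and with control-vs-mutant gaps always > 25 + noise so every
## planted tile is a detectable hypoDMR.
group_truth_box <- function(pair, n) {
    if (pair == 1L) {             # groups 1/2
        psg <- stats::runif(n, 14, 46)
        ctrl <- stats::runif(n, 58, 92)
        dko <- stats::runif(n, 2, 14)
    } else if (pair == 3L) {      # groups 3/4
        psg <- stats::runif(n, 3, 14)
        ctrl <- stats::runif(n, 33, 44)
        dko <- stats::runif(n, 0.5, 3)
    } else {                      # groups 5/6
        psg <- stats::runif(n, 37, 73)
        ctrl <- stats::runif(n, 82, 96)
        dko <- stats::runif(n, 32, pmin(68, ctrl - 33))
    }
    cbind(psg = psg, ctrl = ctrl, dko = dko)
}

rbetabinom <- function(n, size, p, phi) {
    if (phi <= 0) return(stats::rbinom(n, size, p))
    a <- p * (1 - phi) / phi
    b <- (1 - p) * (1 - phi) / phi
    stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate a tiled methylome experiment with planted hypoDMR groups
#'
#' Generates per-CpG methylation counts for prospermatogonia-reference,
#' control and mutant conditions (each with \code{replicates} samples) on a
#' synthetic chromosome of consecutive 500-bp tiles.  Each planted tile
#' draws its percent-methylation triplet from a box strictly interior to
#' its group's classification region; null tiles share one level across
#' conditions.  Per-CpG read depths are Poisson(\code{coverage}) and
#' methylated counts are beta-binomial with (p, \code{phi}).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{cpgs} (reader-format data.frame), \code{tiles}
#'   (annotated \code{GRanges}), \code{samples} (sample_id/condition), and
#'   \code{truth} (tile_id, group, true percentages).
#' @export
simulateMethylome <- function(config) {
    set.seed(config$seed + 101L)
    nG <- config$nTilesPerGroup; n0 <- config$nNullTiles
    groups <- c(rep(1:6, each = nG), rep(0L, n0))
    nT <- length(groups)
    perm <- sample.int(nT)            # interleave planted and null tiles
    groups <- groups[perm]

    truth <- matrix(NA_real_, nT, 3,
                    dimnames = list(NULL, c("psg", "ctrl", "dko")))
    for (pr in c(1L, 3L, 5L)) {
        idx <- which(groups %in% c(pr, pr + 1L))
        if (length(idx)) truth[idx, ] <- group_truth_box(pr, length(idx))
    }
    nulls <- which(groups == 0L)
    p0 <- stats::runif(length(nulls), 5, 95)
    truth[nulls, ] <- cbind(p0, p0, p0)

    gc <- numeric(nT)
    rich <- groups %in% c(1L, 3L, 5L)
    poor <- groups %in% c(2L, 4L, 6L)
    gc[rich] <- stats::runif(sum(rich), 55, 70)
    gc[poor] <- stats::runif(sum(poor), 35, 48)
    gc[groups == 0L] <- stats::runif(sum(groups == 0L), 30, 70)
    n_cpg <- integer(nT)
    n_cpg[gc > 50] <- sample(15:25, sum(gc > 50), replace = TRUE)
    n_cpg[gc <= 50] <- sample(6:14, sum(gc <= 50), replace = TRUE)

    tiles <- makeGenomeTiles(c(chrS = nT * 500L), tileSize = 500L)
    mcols(tiles)$n_cpg <- n_cpg
    mcols(tiles)$gc_percent <- gc

    conds <- c("psg", "ctrl", "dko")
    reps <- config$replicates
    sample_ids <- as.vector(outer(conds, seq_len(reps), paste, sep = "_"))
    cond_of <- rep(conds, reps)

    total_cpgs <- sum(n_cpg)
    pos0 <- unlist(lapply(seq_len(nT), function(i) {
        step <- floor(480 / (n_cpg[i] + 1L))
        (i - 1L) * 500L + 10L + seq_len(n_cpg[i]) * step
    }))
    tile_of_cpg <- rep(seq_len(nT), n_cpg)

    out <- vector("list", length(sample_ids))
    for (s in seq_along(sample_ids)) {
        p_true <- truth[tile_of_cpg, cond_of[s]] / 100
        depth <- stats::rpois(total_cpgs, config$coverage)
        mcount <- rbetabinom(total_cpgs, depth, p_true, config$phi)
        out[[s]] <- data.frame(chrom = "chrS", pos = pos0,
                               count_M = mcount, count_U = depth - mcount,
                               sample_id = sample_ids[s],
                               stringsAsFactors = FALSE)
    }
    cpgs <- do.call(rbind, out)
    cpgs$strand <- "+"
    list(cpgs = cpgs[, c("chrom", "pos", "strand", "count_M", "count_U",
                         "sample_id")],
         tiles = tiles,
         samples = data.frame(sample_id = sample_ids, condition = cond_of,
                              stringsAsFactors = FALSE),
         truth = data.frame(tile_id = mcols(tiles)$tile_id,
                            group = ifelse(groups == 0L, "null",
                                           as.character(groups)),
                            gc_percent = gc, n_cpg = n_cpg,
                            psg = truth[, "psg"], ctrl = truth[, "ctrl"],
                            dko = truth[, "dko"],
                            delta = truth[, "dko"] - truth[, "ctrl"],
                            stringsAsFactors = FALSE))
}

#' Simulate a tiled occupancy experiment
#'
#' Negative-binomial counts for two groups (A = control, B = mutant);
#' planted tiles multiply the group-B mean by \code{2^plantedLfc}.  With
#' \code{bias = TRUE} a smooth intensity-dependent efficiency bias
#' \code{biasAmplitude * sin(A)} (log2 scale, A = true log2 intensity) is
#' applied to the first group-A sample, emulating the between-sample
#' distortion cyclic loess removes.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param bias apply the intensity-dependent bias: \code{FALSE} (default),
#'   \code{TRUE} (first sample only), or the indices of the samples to
#'   distort.  Distorting both samples of one group emulates a group-level
#'   ChIP-efficiency confound — the case differential testing cannot
#'   survive without normalization.
#' @return list with \code{counts} (tiles x samples), \code{group},
#'   \code{librarySize}, and \code{truth} (planted log2fc per tile).
#' @export
simulateOccupancy <- function(config, bias = FALSE) {
    oc <- config$occupancy
    set.seed(config$seed + 202L)
    n <- oc$nTiles
    A <- stats::rnorm(n, oc$meanLog2, oc$sdLog2)   # true log2 intensity
    mu <- 2^A
    lfc <- rep(0, n)
    if (oc$nPlanted > 0)    # balanced signs: gains and losses both occur
        lfc[sample.int(n, oc$nPlanted)] <- oc$plantedLfc *
            sample(c(-1, 1), oc$nPlanted, replace = TRUE)
    biasSamples <- if (isTRUE(bias)) 1L else if (is.numeric(bias)) bias
        else integer(0)
    reps <- oc$replicates
    group <- rep(c("A", "B"), each = reps)
    counts <- matrix(0L, n, 2L * reps)
    colnames(counts) <- paste0(group, rep(seq_len(reps), 2L))
    for (j in seq_len(2L * reps)) {
        m <- if (group[j] == "B") mu * 2^lfc else mu
        if (j %in% biasSamples) m <- m * 2^(oc$biasAmplitude * sin(A))
        counts[, j] <- stats::rnbinom(n, mu = m, size = 1 / oc$dispersion)
    }
    list(counts = counts, group = group, librarySize = colSums(counts),
         truth = data.frame(tile = seq_len(n), log2fc = lfc,
                            intensity_log2 = A))
}

#' Simulate hybrid-cross reads over a SNP-bearing toy chromosome
#'
#' Builds a random reference (paternal) chromosome, plants SNPs at the
#' configured density to form the maternal haplotype, and samples reads
#' from either haplotype with a per-base sequencing error rate.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{reads} (read_id, chrom, pos, seq), \code{snps}
#'   (SNP table, \code{base_ref} = paternal, \code{base_alt} = maternal),
#'   and \code{truth} (read_id, origin).
#' @export
simulateAllelicReads <- function(config) {
    al <- config$allelic
    set.seed(config$seed + 303L)
    len <- al$chromLength
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, len, replace = TRUE)
    nSnp <- round(len * al$snpPer100bp / 100)
    spos <- sort(sample.int(len, nSnp)) - 1L        # 0-based
    alt <- vapply(ref[spos + 1L], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    mat <- ref
    mat[spos + 1L] <- alt
    refS <- paste(ref, collapse = "")
    matS <- paste(mat, collapse = "")

    nR <- al$nReads; rl <- al$readLength
    start <- sample.int(len - rl, nR, replace = TRUE) - 1L   # 0-based
    origin <- sample(c("maternal", "paternal"), nR, replace = TRUE)
    seqs <- ifelse(origin == "maternal",
                   substring(matS, start + 1L, start + rl),
                   substring(refS, start + 1L, start + rl))
    if (al$errorRate > 0) {
        nerr <- stats::rbinom(nR, rl, al$errorRate)
        for (k in which(nerr > 0L)) {
            s <- strsplit(seqs[k], "")[[1L]]
            at <- sample.int(rl, nerr[k])
            s[at] <- vapply(s[at], function(b)
                sample(setdiff(bases, b), 1L), character(1))
            seqs[k] <- paste(s, collapse = "")
        }
    }
    list(reads = data.frame(read_id = sprintf("r%06d", seq_len(nR)),
                            chrom = "chrH", pos = start, seq = seqs,
                            stringsAsFactors = FALSE),
         snps = data.frame(chrom = "chrH", pos = spos, base_ref = ref[spos + 1L],
                           base_alt = alt, stringsAsFactors = FALSE),
         truth = data.frame(read_id = sprintf("r%06d", seq_len(nR)),
                            origin = origin, stringsAsFactors = FALSE))
}

#' Simulate pseudotime-confounded embryo expression counts
#'
#' Per-gene negative-binomial counts whose mean follows a smooth per-gene
#' trend along pseudotime (linear + quadratic components on the log2
#' scale), with the mutant genotype's pseudotimes offset by \code{delay} so
#' developmental progression is confounded with genotype.  A fraction of
#' genes additionally carries a genuine genotype effect of
#' \code{effectLfc} log2 units (random sign).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{counts} (genes x samples), \code{genotype},
#'   \code{pst}, \code{librarySize}, and \code{truth} (per-gene planted
#'   log2fc and trend coefficients).
#' @export
simulateExpression <- function(config) {
    ex <- config$expression
    set.seed(config$seed + 404L)
    nG <- ex$nGenes; np <- ex$nPerGenotype
    genotype <- rep(c("ctrl", "ko"), each = np)
    ## systematic developmental delay: evenly spaced pseudotimes with the
    ## mutant cohort shifted by `delay`, plus a small jitter
    grid <- seq(0.05, 0.65, length.out = np)
    pst <- c(grid, grid + ex$delay) + stats::runif(2L * np, -0.02, 0.02)
    base <- 2^stats::rnorm(nG, ex$baseMeanLog2, ex$baseSdLog2)
    beta <- stats::rnorm(nG, 0, ex$trendSd)
    gamma <- stats::rnorm(nG, 0, ex$curveSd)
    lfc <- rep(0, nG)
    nEff <- round(ex$effectFraction * nG)
    if (nEff > 0)
        lfc[sample.int(nG, nEff)] <- ex$effectLfc *
            sample(c(-1, 1), nEff, replace = TRUE)
    isKo <- as.numeric(genotype == "ko")
    logmu <- outer(beta, pst) + outer(gamma, pst^2) + outer(lfc, isKo) +
        log2(base)
    mu <- 2^logmu
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / ex$dispersion),
                     nG, length(pst))
    rownames(counts) <- sprintf("g%05d", seq_len(nG))
    colnames(counts) <- paste0(genotype, "_", rep(seq_len(np), 2L))
    list(counts = counts, genotype = genotype, pst = pst,
         librarySize = colSums(counts),
         truth = data.frame(gene = rownames(counts), log2fc = lfc,
                            trend_beta = beta, trend_gamma = gamma,
                            stringsAsFactors = FALSE))
}
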