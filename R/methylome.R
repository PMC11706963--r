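#' Read per-CpG methylation counts
#'
#' Reads a TSV with columns \code{chrom, pos, strand, count_M, count_U,
#' sample_id} (header optional, detected from the first line).  Positions are
#' the 0-based coordinate of the C of the CpG on the plus strand; records on
#' the minus strand are shifted back by one base and merged with their plus
#' strand partner (destranding), leaving one record per CpG per sample.
#'
#' The \code{"rrbs"} dialect additionally discards CpGs covered by fewer than
#' 5 reads (per sample), matching reduced-representation processing; the
#' \code{"emseq"} dialect keeps all covered CpGs.
#'
#' @param path TSV file path, or a data.frame with the same columns.
#' @param dialect \code{"emseq"} or \code{"rrbs"}.
#' @param oneBased set \code{TRUE} if input positions are 1-based.
#' @param minReadsPerCpg coverage filter applied by the rrbs dialect
#'   (default 5).
#' @return A data.frame with columns \code{chrom, pos, count_M, count_U,
#'   sample_id}, destranded, 0-based positions.
#' @export
readCpgCounts <- function(path, dialect = c("emseq", "rrbs"),
                          oneBased = FALSE, minReadsPerCpg = 5L) {
    dialect <- match.arg(dialect)
    df <- if (is.data.frame(path)) path else {
        first <- readLines(path, n = 1L)
        has_header <- grepl("chrom", first, fixed = TRUE)
        utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
    }
    if (!"sample_id" %in% names(df) && ncol(df) >= 5L) {
        names(df)[1:5] <- c("chrom", "pos", "strand", "count_M", "count_U")
        if (ncol(df) >= 6L) names(df)[6L] <- "sample_id"
        else df$sample_id <- "sample1"
    }
    bad <- which(df$count_M < 0 | df$count_U < 0)
    if (length(bad))
        stop("negative counts at line ", bad[1L])
    bads <- which(!df$strand %in% c("+", "-", "*"))
    if (length(bads))
        stop("unknown strand symbol at line ", bads[1L])
    if (oneBased) df$pos <- df$pos - 1L
    # minus-strand record sits on the G: shift back to the C of the CpG
    df$pos <- ifelse(df$strand == "-", df$pos - 1L, df$pos)
    agg <- stats::aggregate(cbind(count_M, count_U) ~ chrom + pos + sample_id,
                            data = df, FUN = sum)
    if (dialect == "rrbs")
        agg <- agg[agg$count_M + agg$count_U >= minReadsPerCpg, , drop = FALSE]
    rownames(agg) <- NULL
    agg[order(agg$sample_id, agg$chrom, agg$pos),
        c("chrom", "pos", "count_M", "count_U", "sample_id")]
}

#' Aggregate per-CpG counts to genomic tiles
#'
#' Sums methylated and total (M+U) read counts of all CpGs falling inside
#' each tile, per sample.  CpGs outside every tile are left unassigned; their
#' number is recorded in \code{metadata(result)$n_unassigned}.
#'
#' @param cpgs destranded data.frame from \code{\link{readCpgCounts}}.
#' @param tiles annotated \code{GRanges} of tiles.
#' @return A \linkS4class{TileMethylation} with one column per
#'   \code{sample_id}.
#' @export
aggregateToTiles <- function(cpgs, tiles) {
    gr <- GRanges(cpgs$chrom, IRanges(cpgs$pos + 1L, cpgs$pos + 1L))
    hits <- findOverlaps(gr, tiles)
    samples <- sort(unique(cpgs$sample_id))
    nT <- length(tiles)
    m <- matrix(0, nT, length(samples), dimnames = list(NULL, samples))
    t <- m
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sj <- match(cpgs$sample_id[qi], samples)
    mm <- cpgs$count_M[qi]; tt <- mm + cpgs$count_U[qi]
    lin <- si + (sj - 1L) * nT     # linear cell index, accumulated by rowsum
    accM <- rowsum(mm, lin); accT <- rowsum(tt, lin)
    cells <- as.integer(rownames(accM))
    m[cells] <- accM[, 1L]
    t[cells] <- accT[, 1L]
    tm <- TileMethylation(m, t, tiles)
    metadata(tm)$n_unassigned <- nrow(cpgs) - length(unique(qi))
    tm
}

#' Filter tiles eligible for differential testing
#'
#' Keeps tiles with at least \code{minCpg} annotated CpGs and at least
#' \code{minReads} total CpG reads in \emph{every} sample (the per-sample
#' reading of the coverage rule: the stricter, reproducible interpretation).
#' Presets: whole-genome enzymatic data use \code{minReads = 25}; RRBS uses
#' \code{minReads = 20}.
#'
#' @param tm a \linkS4class{TileMethylation}.
#' @param minCpg minimum annotated CpGs per tile (default 5).
#' @param minReads minimum total reads per tile in each sample (default 25).
#' @return The filtered \code{TileMethylation}.
#' @export
filterTiles <- function(tm, minCpg = 5L, minReads = 25L) {
    ncpg <- rowRanges(tm)$n_cpg
    if (is.null(ncpg)) stop("tiles must be annotated with n_cpg")
    keep <- ncpg >= minCpg &
        apply(assay(tm, "total") >= minReads, 1L, all)
    tm[keep, ]
}

## beta-binomial log-likelihood for tile-level (m, t) with mean p and
## overdispersion phi in [0, 1); phi = 0 reduces to the binomial.
bb_loglik <- function(m, t, p, phi) {
    p <- min(max(p, 1e-9), 1 - 1e-9)
    if (phi <= 0)
        return(sum(stats::dbinom(m, t, p, log = TRUE)))
    a <- p * (1 - phi) / phi
    b <- (1 - p) * (1 - phi) / phi
    sum(lchoose(t, m) + lbeta(m + a, t - m + b) - lbeta(a, b))
}

bb_mle <- function(m, t, phi) {
    phat <- sum(m) / sum(t)
    if (phi <= 0) return(list(p = phat, ll = bb_loglik(m, t, phat, 0)))
    opt <- stats::optimize(function(p) bb_loglik(m, t, p, phi),
                           interval = c(1e-6, 1 - 1e-6), maximum = TRUE,
                           tol = 1e-8)
    list(p = opt$maximum, ll = opt$objective)
}

## Moment estimate of tile-level overdispersion from replicate proportions.
## For replicate counts (m_i, t_i) around a group mean p:
##   Var(m_i/t_i) = p(1-p)/t_i * (1 + (t_i - 1) phi)
## Summing squared group-centred residuals over replicates and solving for
## phi gives the estimator below; values are floored at 0.
phi_moment <- function(m, t, group) {
    ok <- t > 0
    m <- m[ok]; t <- t[ok]; group <- group[ok]
    if (length(t) < 3L) return(NA_real_)
    p_g <- tapply(m, group, sum) / tapply(t, group, sum)
    p_i <- p_g[match(group, names(p_g))]
    r2 <- (m / t - p_i)^2
    v <- p_i * (1 - p_i)
    df <- length(t) - length(unique(group))
    if (df <= 0 || all(v == 0)) return(NA_real_)
    ## solve E[sum(r2)] = cc * [ sum(v/t) + phi * sum(v (t-1)/t) ],
    ## cc = df/n accounting for the group-mean centring
    cc <- df / length(t)
    denom <- sum(v * (t - 1) / t)
    if (denom <= 0) return(NA_real_)
    max(0, (sum(r2) / cc - sum(v / t)) / denom)
}

#' Beta-binomial likelihood-ratio test for differential methylation
#'
#' For each tile, tests whether the methylation proportion differs between
#' two groups of samples using a likelihood-ratio test of a beta-binomial
#' model with common versus group-specific mean, referred to chi-square with
#' one degree of freedom.  Overdispersion \code{phi} is estimated by the
#' method of moments from replicate-level proportions; by default the
#' tile-wise moment estimates are pooled into a single common value
#' (precision of the tile-wise estimator with few replicates is far too low
#' to calibrate the test), with \code{phi = "tilewise"} available.  When
#' \code{phi} is 0 (or not estimable) the test reduces to a binomial LRT.
#'
#' The effect size \code{delta_me} is the replicate-pooled percent
#' methylation of group B minus group A, in percentage points.
#'
#' @param tm a filtered \linkS4class{TileMethylation}.
#' @param groupA,groupB column names or indices of the two sample groups
#'   (A = reference, B = test).
#' @param phi \code{"common"} (default), \code{"tilewise"}, or a fixed
#'   numeric value.
#' @return A data.frame with \code{tile_id, delta_me, p_value, fdr,
#'   dispersion_phi}; tiles with zero coverage in a whole group are skipped
#'   (returned with \code{NA} and excluded from the BH adjustment).
#' @export
testDifferentialMethylation <- function(tm, groupA, groupB, phi = "common") {
    M <- assay(tm, "meth"); T <- assay(tm, "total")
    a <- M[, groupA, drop = FALSE]; ta <- T[, groupA, drop = FALSE]
    b <- M[, groupB, drop = FALSE]; tb <- T[, groupB, drop = FALSE]
    n <- nrow(M)
    grp <- rep(c("A", "B"), c(ncol(a), ncol(b)))
    mAll <- cbind(a, b); tAll <- cbind(ta, tb)

    phi_tile <- vapply(seq_len(n), function(i)
        phi_moment(mAll[i, ], tAll[i, ], grp), numeric(1))
    if (identical(phi, "common")) {
        phi_use <- rep(mean(phi_tile, na.rm = TRUE), n)
        if (all(is.na(phi_tile))) phi_use <- rep(0, n)
    } else if (identical(phi, "tilewise")) {
        phi_use <- ifelse(is.na(phi_tile), 0, phi_tile)
    } else {
        phi_use <- rep(as.numeric(phi), n)
    }
    phi_use[!is.finite(phi_use) | phi_use < 0] <- 0
    phi_use <- pmin(phi_use, 0.999)

    pA <- rowSums(a) / pmax(rowSums(ta), 1)
    pB <- rowSums(b) / pmax(rowSums(tb), 1)
    delta <- 100 * (pB - pA)
    skip <- rowSums(ta) == 0 | rowSums(tb) == 0
    delta[skip] <- NA_real_

    pval <- rep(NA_real_, n)
    for (i in which(!skip)) {
        mi <- mAll[i, ]; ti <- tAll[i, ]; ph <- phi_use[i]
        ll0 <- bb_mle(mi, ti, ph)$ll
        llA <- bb_mle(mi[grp == "A"], ti[grp == "A"], ph)$ll
        llB <- bb_mle(mi[grp == "B"], ti[grp == "B"], ph)$ll
        lrt <- max(0, 2 * (llA + llB - ll0))
        pval[i] <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
    }
    data.frame(tile_id = rowRanges(tm)$tile_id,
               delta_me = delta,
               p_value = pval,
               fdr = bhAdjust(pval),
               dispersion_phi = phi_use,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; missing p-values are propagated as missing and
#' excluded from the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted values, clipped at 1, monotone in the sorted order.
#' @export
bhAdjust <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Call differentially methylated regions
#'
#' A tile is \code{hypo} if \code{delta_me < -deltaThreshold} and
#' \code{fdr < fdrThreshold} (test group losing methylation), \code{hyper}
#' for the opposite sign, \code{none} otherwise.  The RRBS preset uses
#' \code{deltaThreshold = 20}.
#'
#' @param records data.frame from \code{\link{testDifferentialMethylation}}.
#' @param deltaThreshold minimum absolute methylation difference in
#'   percentage points (default 25).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return \code{records} with a \code{direction} factor plus an attached
#'   \code{"summary"} attribute (n examined / significant / hypo / hyper).
#' @export
callDmrs <- function(records, deltaThreshold = 25, fdrThreshold = 0.05) {
    dir <- rep("none", nrow(records))
    sig <- !is.na(records$fdr) & records$fdr < fdrThreshold
    dir[sig & records$delta_me < -deltaThreshold] <- "hypo"
    dir[sig & records$delta_me > deltaThreshold] <- "hyper"
    records$direction <- factor(dir, levels = c("hypo", "none", "hyper"))
    n_sig <- sum(dir != "none")
    attr(records, "summary") <- list(
        n_examined = sum(!is.na(records$p_value)),
        n_significant = n_sig,
        n_hypo = sum(dir == "hypo"),
        n_hyper = sum(dir == "hyper"))
    records
}
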