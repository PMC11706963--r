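#' log2 RPKM of tile counts
#'
#' \code{log2((count + pseudocount) / (tileLength/1000 * librarySize/1e6))}.
#' The pseudocount (default 0.5) keeps zero-count tiles finite; with the
#' defaults a zero count in a 500-bp tile at 1e6 library reads maps to 0.
#'
#' @param counts matrix (tiles x samples) of raw counts, or a
#'   \linkS4class{TileOccupancy}.
#' @param librarySize per-sample library sizes (total or allelic read
#'   counts); taken from the object when \code{counts} is a TileOccupancy.
#' @param tileLength tile width in bp.
#' @param pseudocount added to every count (default 0.5).
#' @return matrix of log2 RPKM values.
#' @export
log2Rpkm <- function(counts, librarySize = NULL, tileLength = 500,
                     pseudocount = 0.5) {
    if (is(counts, "TileOccupancy")) {
        librarySize <- librarySizes(counts)
        tileLength <- metadata(counts)$tile_length
        counts <- occupancyCounts(counts)
    }
    counts <- as.matrix(counts)
    if (is.null(librarySize)) stop("librarySize is required")
    if (any(librarySize <= 0)) stop("zero or negative library size")
    denom <- (tileLength / 1000) * (librarySize / 1e6)
    log2(sweep(counts + pseudocount, 2L, denom, "/"))
}

#' Invert log2 RPKM back to (pseudo-)counts
#'
#' Used to hand normalized values back to the count-based differential test;
#' results are floored at 0 (normalization can push low values below the
#' pseudocount).
#'
#' @param log2rpkm matrix from \code{\link{log2Rpkm}}.
#' @inheritParams log2Rpkm
#' @return matrix of non-negative pseudo-counts.
#' @export
rpkmToCounts <- function(log2rpkm, librarySize, tileLength = 500,
                         pseudocount = 0.5) {
    denom <- (tileLength / 1000) * (librarySize / 1e6)
    pmax(sweep(2^log2rpkm, 2L, denom, "*") - pseudocount, 0)
}

#' Fast cyclic-loess normalization
#'
#' Removes smooth intensity-dependent differences between samples.  The fast
#' variant fits, for each sample s, a robust tricube-weighted local
#' regression (\code{stats::lowess} with robustness iterations, so a small
#' fraction of genuinely changed tiles does not drag the fit) of
#' \code{M_s = x_s - A} on the per-tile mean \code{A} and subtracts the
#' fit.  Fits are re-centred across samples before subtraction, so the
#' per-tile cross-sample mean is preserved exactly; between-sample
#' differences are unaffected by the centring.
#'
#' @param x matrix of log2 RPKM values (tiles x samples), >= 2 columns.
#' @param span smoother span (fraction of tiles per window, default 0.7).
#' @param iterations number of passes over the samples (default 1).
#' @param robustIter robustness iterations of the local fit (default 3).
#' @param trim drop tiles with fit residuals beyond 2 robust SD and refit,
#'   so genuinely changed tiles do not compress the correction curve
#'   (default TRUE; with FALSE the fit is the plain fast cyclic loess).
#' @return normalized matrix; attribute \code{"max_mean_drift"} reports the
#'   largest per-tile mean change (0 up to rounding).
#' @export
cyclicLoessNormalize <- function(x, span = 0.7, iterations = 1L,
                                 robustIter = 3L, trim = TRUE) {
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("need at least 2 samples")
    if (nrow(x) < 50L)
        stop("too few tiles for loess support; increase span or tile count")
    mean0 <- rowMeans(x)
    for (it in seq_len(iterations)) {
        A <- rowMeans(x)
        fits <- vapply(seq_len(ncol(x)), function(j) {
            M <- x[, j] - A
            f <- stats::lowess(A, M, f = span, iter = robustIter)
            fit <- stats::approx(f$x, f$y, xout = A, rule = 2,
                                 ties = mean)$y
            r <- M - fit
            keep <- !trim | abs(r) <= 2 * stats::mad(r)
            if (trim && sum(keep) >= 50L && any(!keep)) {
                f <- stats::lowess(A[keep], M[keep], f = span,
                                   iter = robustIter)
                fit <- stats::approx(f$x, f$y, xout = A, rule = 2,
                                     ties = mean)$y
            }
            fit
        }, numeric(nrow(x)))
        fits <- fits - rowMeans(fits)   # centring preserves per-tile means
        x <- x - fits
    }
    attr(x, "max_mean_drift") <- max(abs(rowMeans(x) - mean0))
    x
}

#' Normalize a TileOccupancy object
#'
#' Computes log2 RPKM and applies \code{\link{cyclicLoessNormalize}}, storing
#' the result as the \code{"log2rpkm"} assay.
#'
#' @param x a \linkS4class{TileOccupancy}.
#' @inheritParams cyclicLoessNormalize
#' @param pseudocount passed to \code{\link{log2Rpkm}}.
#' @return \code{x} with a \code{"log2rpkm"} assay and
#'   \code{metadata(x)$normalized = TRUE}.
#' @export
normalizeOccupancy <- function(x, span = 0.7, iterations = 1L,
                               pseudocount = 0.5) {
    lr <- log2Rpkm(x, pseudocount = pseudocount)
    norm <- cyclicLoessNormalize(lr, span = span, iterations = iterations)
    assays(x)$log2rpkm <- norm
    metadata(x)$normalized <- TRUE
    x
}

## Common NB dispersion from Pearson residuals around group means: solve
## sum (x - mu)^2 / (mu + disp mu^2) = total residual df (the Pearson
## moment equation, shared across all tiles). Floored at 0 (Poisson).
estimateCommonDispersion <- function(counts, group, offset = NULL) {
    counts <- as.matrix(counts)
    n <- ncol(counts)
    if (is.null(offset)) offset <- rep(0, n)
    sf <- exp(offset - mean(offset))
    y <- sweep(counts, 2L, sf, "/")      # scale-adjusted counts
    groups <- unique(group)
    mu <- matrix(0, nrow(counts), n)
    p <- length(groups)
    for (g in groups) {
        j <- group == g
        mu[, j] <- rowMeans(y[, j, drop = FALSE])
    }
    mu_raw <- sweep(mu, 2L, sf, "*")
    keep <- rowSums(mu_raw) > 0 & rowSums(mu_raw == 0) == 0
    res2 <- (counts - mu_raw)[keep, , drop = FALSE]^2
    mu_raw <- mu_raw[keep, , drop = FALSE]
    target <- nrow(mu_raw) * (n - p)
    pearson <- function(disp) sum(res2 / (mu_raw + disp * mu_raw^2)) - target
    if (pearson(0) <= 0) return(0)
    if (pearson(10) > 0) return(10)
    stats::uniroot(pearson, c(0, 10), tol = 1e-6)$root
}

## Vectorized NB mean fit with fixed dispersion and per-sample scale
## factors: solves sum_j (x_ij - m_i sf_j) / (1 + phi m_i sf_j) = 0 for
## every tile i at once by Newton iteration (the NB score equation for a
## common mean with offsets).  Returns the profile log-likelihood per tile.
nb_profile_ll <- function(counts, sf, phi) {
    m <- pmax(rowSums(counts) / sum(sf), 1e-8)
    if (phi > 1e-8) {
        for (it in 1:50) {
            mu <- outer(m, sf)
            g <- rowSums((counts - mu) / (1 + phi * mu))
            gp <- -rowSums(sweep((1 + phi * counts) / (1 + phi * mu)^2,
                                 2L, sf, "*"))
            step <- g / gp
            m_new <- pmax(m - step, m / 10)
            if (max(abs(m_new - m) / (m + 1e-8)) < 1e-10) { m <- m_new; break }
            m <- m_new
        }
        mu <- outer(m, sf)
        ll <- rowSums(stats::dnbinom(counts, mu = mu, size = 1 / phi,
                                     log = TRUE))
    } else {
        mu <- outer(m, sf)
        ll <- rowSums(stats::dpois(counts, mu, log = TRUE))
    }
    ll
}

## Two-group NB likelihood-ratio test with fixed common dispersion and
## per-sample offsets (log library size).
nb_lrt_two_group <- function(counts, group, offset, dispersion) {
    counts <- round(as.matrix(counts))
    sf <- exp(offset - mean(offset))
    jA <- group == unique(group)[1L]
    ll1 <- nb_profile_ll(counts[, jA, drop = FALSE], sf[jA], dispersion) +
        nb_profile_ll(counts[, !jA, drop = FALSE], sf[!jA], dispersion)
    ll0 <- nb_profile_ll(counts, sf, dispersion)
    lrt <- pmax(0, 2 * (ll1 - ll0))
    stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
}

#' Differential occupancy between two sample groups
#'
#' Normalized log2 RPKM values are transformed back to pseudo-counts, and
#' each tile is tested with a two-group negative-binomial likelihood-ratio
#' test using a single common dispersion estimated across tiles by the
#' method of moments on Pearson residuals.  The fold change is computed on
#' the CPM scale with a stabilizing prior count:
#' \code{log2fc = log2((meanCPM_B + priorCount)/(meanCPM_A + priorCount))}.
#' A tile is \code{significant} when \code{|log2fc| > lfcThreshold} and
#' \code{p < pThreshold}; p-values are raw by default (set
#' \code{adjust = TRUE} for BH).
#'
#' @param normA,normB normalized log2 RPKM matrices for groups A and B
#'   (same rows).
#' @param librarySizesA,librarySizesB per-sample library sizes.
#' @param tileLength tile width in bp.
#' @param priorCount prior count for fold changes (default 1).
#' @param pseudocount the log2 RPKM pseudocount used upstream (default 0.5).
#' @param lfcThreshold,pThreshold significance cutoffs (defaults 1, 0.05).
#' @param adjust apply BH to the p-values before thresholding (default
#'   FALSE: raw p, as in the occupancy contrasts).
#' @return data.frame with \code{log2fc, p_value, significant, lfc_class}
#'   (trichotomized at ±0.5, see \code{\link{trichotomizeLfc}}).
#' @export
testDifferentialOccupancy <- function(normA, normB, librarySizesA,
                                      librarySizesB, tileLength = 500,
                                      priorCount = 1, pseudocount = 0.5,
                                      lfcThreshold = 1, pThreshold = 0.05,
                                      adjust = FALSE) {
    normA <- as.matrix(normA); normB <- as.matrix(normB)
    stopifnot(nrow(normA) == nrow(normB))
    cA <- rpkmToCounts(normA, librarySizesA, tileLength, pseudocount)
    cB <- rpkmToCounts(normB, librarySizesB, tileLength, pseudocount)
    if (all(cA == 0) || all(cB == 0))
        stop("a group has zero counts everywhere; check library sizes")
    cpmA <- sweep(cA, 2L, librarySizesA / 1e6, "/")
    cpmB <- sweep(cB, 2L, librarySizesB / 1e6, "/")
    log2fc <- log2((rowMeans(cpmB) + priorCount) /
                   (rowMeans(cpmA) + priorCount))
    counts <- cbind(cA, cB)
    group <- rep(c("A", "B"), c(ncol(cA), ncol(cB)))
    offset <- log(c(librarySizesA, librarySizesB))
    disp <- estimateCommonDispersion(round(counts), group, offset)
    p <- nb_lrt_two_group(counts, group, offset, disp)
    padj <- if (adjust) bhAdjust(p) else p
    data.frame(log2fc = log2fc, p_value = p,
               significant = abs(log2fc) > lfcThreshold & padj < pThreshold,
               lfc_class = trichotomizeLfc(log2fc),
               dispersion = disp)
}

#' Trichotomize log2 fold changes
#'
#' \code{increased} above \code{+bound}, \code{reduced} below \code{-bound}
#' (strict inequalities; values at exactly ±bound are \code{unaltered}).
#'
#' @param log2fc numeric vector.
#' @param bound class boundary (default 0.5).
#' @return factor with levels \code{reduced}, \code{unaltered},
#'   \code{increased}.
#' @export
trichotomizeLfc <- function(log2fc, bound = 0.5) {
    out <- rep("unaltered", length(log2fc))
    out[log2fc > bound] <- "increased"
    out[log2fc < -bound] <- "reduced"
    factor(out, levels = c("reduced", "unaltered", "increased"))
}

#' Filter externally called peaks
#'
#' Keeps peaks with \code{q < qMax} and length strictly below the
#' \code{lengthQuantile} (type-7) quantile of the input peak lengths, and
#' recomputes summary statistics.
#'
#' @param peaks data.frame with columns \code{chrom, start, end, q_value}
#'   (0-based half-open).
#' @param qMax q-value cutoff (default 0.01).
#' @param lengthQuantile quantile of input lengths used as the length cap
#'   (default 0.99).
#' @param genomeSize total genome size in bp for the coverage fraction.
#' @return list with \code{peaks} (filtered) and \code{summary}
#'   (\code{n_peaks}, \code{fraction_genome_covered}, \code{median_length}).
#' @export
filterPeaks <- function(peaks, qMax = 0.01, lengthQuantile = 0.99,
                        genomeSize = NA_real_) {
    if (nrow(peaks) == 0L)
        return(list(peaks = peaks,
                    summary = list(n_peaks = 0L,
                                   fraction_genome_covered = 0,
                                   median_length = NA_real_)))
    len <- peaks$end - peaks$start
    if (any(len <= 0)) stop("peak with non-positive length")
    cap <- stats::quantile(len, lengthQuantile, type = 7, names = FALSE)
    keep <- peaks$q_value < qMax & len < cap
    out <- peaks[keep, , drop = FALSE]
    lenk <- out$end - out$start
    list(peaks = out,
         summary = list(
             n_peaks = nrow(out),
             fraction_genome_covered =
                 if (is.na(genomeSize)) NA_real_ else sum(lenk) / genomeSize,
             median_length = if (nrow(out)) stats::median(lenk) else NA_real_))
}
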