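#' Natural cubic spline basis for a pseudotime vector
#'
#' Boundary knots at the range of \code{x}, internal knots at the 1/3 and
#' 2/3 quantiles (df = 3 columns for the default).  Placing internal knots
#' at pseudotime quantiles keeps the basis identifiable with a dozen
#' embryos, while the natural constraint makes the fitted trend linear
#' beyond the observed pseudotime range.
#'
#' @param x numeric pseudotime vector.
#' @param df number of basis columns (default 3, giving df - 1 internal
#'   knots).
#' @return matrix with \code{df} columns (a \code{splines::ns} basis).
#' @export
naturalSplineBasis <- function(x, df = 3L) {
    if (length(unique(x)) < df + 1L)
        stop("need more distinct pseudotime values than spline df")
    probs <- seq_len(df - 1L) / df
    knots <- stats::quantile(x, probs, names = FALSE, type = 7)
    splines::ns(x, knots = knots, Boundary.knots = range(x))
}

#' Counts per million
#'
#' @param counts matrix (genes x samples).
#' @param librarySize per-sample totals; defaults to column sums.
#' @return CPM matrix.
#' @export
cpmMatrix <- function(counts, librarySize = colSums(counts)) {
    sweep(as.matrix(counts), 2L, librarySize / 1e6, "/")
}

## NB GLM likelihood-ratio test of designFull vs designReduced per gene,
## fixed common dispersion, offset = log library size.
nb_glm_lrt <- function(counts, designFull, designReduced, offset,
                       dispersion) {
    counts <- round(as.matrix(counts))
    fam <- if (dispersion <= 1e-8) stats::poisson() else
        MASS::negative.binomial(theta = 1 / dispersion)
    qrF <- qr(designFull)
    if (qrF$rank < ncol(designFull))
        stop("non-identifiable design: column(s) ",
             paste(colnames(designFull)[qrF$pivot[-seq_len(qrF$rank)]],
                   collapse = ", "), " are collinear")
    ng <- nrow(counts)
    p <- numeric(ng); coefF <- matrix(NA_real_, ng, ncol(designFull))
    colnames(coefF) <- colnames(designFull)
    dfd <- ncol(designFull) - ncol(designReduced)
    for (i in seq_len(ng)) {
        y <- counts[i, ]
        f1 <- suppressWarnings(stats::glm.fit(designFull, y, family = fam,
                                              offset = offset))
        f0 <- suppressWarnings(stats::glm.fit(designReduced, y, family = fam,
                                              offset = offset))
        lrt <- max(0, f0$deviance - f1$deviance)
        p[i] <- stats::pchisq(lrt, df = dfd, lower.tail = FALSE)
        coefF[i, ] <- f1$coefficients
    }
    list(p = p, coef = coefF)
}

## Common dispersion for a GLM design: fitted means from per-gene Poisson
## fits, then one shared dispersion solving the Pearson moment equation
## sum (x - mu)^2 / (mu + disp mu^2) = total residual df.
common_dispersion_glm <- function(counts, design, offset) {
    counts <- round(as.matrix(counts))
    n <- ncol(counts); pcols <- ncol(design)
    mus <- matrix(NA_real_, nrow(counts), n)
    for (i in seq_len(nrow(counts))) {
        f <- suppressWarnings(stats::glm.fit(design, counts[i, ],
                                             family = stats::poisson(),
                                             offset = offset))
        mus[i, ] <- f$fitted.values
    }
    keep <- rowSums(mus <= 0) == 0
    res2 <- (counts - mus)[keep, , drop = FALSE]^2
    mus <- mus[keep, , drop = FALSE]
    target <- nrow(mus) * (n - pcols)
    pearson <- function(disp) sum(res2 / (mus + disp * mus^2)) - target
    if (pearson(0) <= 0) return(0)
    if (pearson(10) > 0) return(10)
    stats::uniroot(pearson, c(0, 10), tol = 1e-6)$root
}

#' Two-group differential expression (negative binomial LRT)
#'
#' Genes whose CPM never reaches 1 in any sample are excluded, then each
#' gene is tested with a two-group NB likelihood-ratio test using a common
#' dispersion (moment estimator across genes).  Fold changes use a prior
#' count of 1 on the CPM scale; significance requires \code{|log2fc| > 1}
#' and BH FDR < 0.05.
#'
#' @param counts matrix (genes x samples).
#' @param groups two-level factor/vector over samples; the fold change is
#'   second level over first.
#' @param librarySize per-sample totals (default column sums).
#' @param minCpm CPM filter threshold (default 1).
#' @param lfcThreshold,fdrThreshold significance cutoffs (1, 0.05).
#' @param priorCount prior count for fold changes (default 1).
#' @return data.frame with \code{id, log2fc, p, fdr, significant}; filtered
#'   genes are absent.
#' @export
deTwoGroup <- function(counts, groups, librarySize = colSums(counts),
                       minCpm = 1, lfcThreshold = 1, fdrThreshold = 0.05,
                       priorCount = 1) {
    counts <- as.matrix(counts)
    g <- factor(groups)
    stopifnot(nlevels(g) == 2L)
    cpm <- cpmMatrix(counts, librarySize)
    keep <- apply(cpm, 1L, max) >= minCpm
    counts <- counts[keep, , drop = FALSE]
    cpm <- cpm[keep, , drop = FALSE]
    offset <- log(librarySize)
    X1 <- stats::model.matrix(~0 + g)
    X0 <- matrix(1, ncol(counts), 1L)
    disp <- estimateCommonDispersion(counts, as.character(g), offset)
    fit <- nb_glm_lrt(counts, X1, X0, offset, disp)
    mA <- rowMeans(cpm[, g == levels(g)[1L], drop = FALSE])
    mB <- rowMeans(cpm[, g == levels(g)[2L], drop = FALSE])
    log2fc <- log2((mB + priorCount) / (mA + priorCount))
    fdr <- bhAdjust(fit$p)
    data.frame(id = rownames(counts) %||% as.character(which(keep)),
               log2fc = log2fc, p = fit$p, fdr = fdr,
               significant = abs(log2fc) > lfcThreshold & fdr < fdrThreshold,
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudotime-adjusted differential expression
#'
#' Fits, per gene, a negative-binomial GLM (log link, offset log library
#' size) with design \code{~ 0 + genotype + ns(pst, 3)} and tests the
#' genotype contrast with a likelihood-ratio test against a reduced design
#' in which the two genotype columns are pooled into one (df = 1).  The
#' spline absorbs smooth expression changes along developmental pseudotime,
#' so genotype effects are not confounded with developmental delay.
#' Dispersion is a single common moment estimate; p-values are
#' BH-adjusted.
#'
#' @param counts matrix (genes x samples).
#' @param genotype two-level factor/vector; the fold change is second level
#'   over first.
#' @param pst numeric pseudotime per sample.
#' @param librarySize per-sample totals (default column sums).
#' @param splineDf spline df (default 3).
#' @param minCpm CPM filter (default 1).
#' @param lfcThreshold,fdrThreshold significance cutoffs (1, 0.05).
#' @return data.frame with \code{id, log2fc, p, fdr, significant}.
#' @export
dePseudotimeAdjusted <- function(counts, genotype, pst,
                                 librarySize = colSums(counts),
                                 splineDf = 3L, minCpm = 1,
                                 lfcThreshold = 1, fdrThreshold = 0.05) {
    counts <- as.matrix(counts)
    g <- factor(genotype)
    stopifnot(nlevels(g) == 2L, length(pst) == ncol(counts))
    if (length(unique(pst)) < splineDf + 1L)
        stop("non-identifiable design: pseudotime has too few distinct ",
             "values to separate genotype from the spline")
    cpm <- cpmMatrix(counts, librarySize)
    keep <- apply(cpm, 1L, max) >= minCpm
    counts <- counts[keep, , drop = FALSE]
    basis <- naturalSplineBasis(pst, df = splineDf)
    colnames(basis) <- paste0("ns", seq_len(ncol(basis)))
    G <- stats::model.matrix(~0 + g)
    colnames(G) <- levels(g)
    XF <- cbind(G, basis)
    XR <- cbind(pooled = 1, basis)
    offset <- log(librarySize)
    disp <- common_dispersion_glm(counts, XF, offset)
    fit <- nb_glm_lrt(counts, XF, XR, offset, disp)
    log2fc <- (fit$coef[, levels(g)[2L]] - fit$coef[, levels(g)[1L]]) / log(2)
    fdr <- bhAdjust(fit$p)
    data.frame(id = rownames(counts) %||% as.character(which(keep)),
               log2fc = log2fc, p = fit$p, fdr = fdr,
               significant = abs(log2fc) > lfcThreshold & fdr < fdrThreshold,
               stringsAsFactors = FALSE)
}

#' Permuted-pseudotime overfitting control
#'
#' Re-runs \code{\link{dePseudotimeAdjusted}} with the pseudotime vector
#' randomly permuted across samples and records the number of significant
#' genes per permutation — an excess of the observed count over the
#' permuted distribution guards against spline overfitting.
#'
#' @inheritParams dePseudotimeAdjusted
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @return list with \code{observed} (significant-gene count) and
#'   \code{permuted} (integer vector of length \code{nPerm}).
#' @export
permutationControl <- function(counts, genotype, pst, nPerm, seed,
                               librarySize = colSums(counts), ...) {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (missing(seed)) stop("seed is required")
    obs <- sum(dePseudotimeAdjusted(counts, genotype, pst,
                                    librarySize = librarySize,
                                    ...)$significant)
    set.seed(seed)
    perms <- vapply(seq_len(nPerm), function(i) {
        ps <- sample(pst)
        sum(dePseudotimeAdjusted(counts, genotype, ps,
                                 librarySize = librarySize,
                                 ...)$significant)
    }, integer(1))
    list(observed = obs, permuted = perms)
}

#' Stratify regions by a reference expression level
#'
#' Quantile bins (type-7) of the reference values; ties at a boundary fall
#' into the lower stratum.  Constant references collapse to stratum 1 with
#' a warning.
#'
#' @param reference numeric vector (e.g. control-embryo expression per
#'   region).
#' @param nStrata number of strata (default 4: quartiles).
#' @return integer stratum labels in \code{1..nStrata}.
#' @export
stratifyByExpression <- function(reference, nStrata = 4L) {
    qs <- stats::quantile(reference, probs = seq_len(nStrata - 1L) / nStrata,
                          type = 7, names = FALSE)
    if (length(unique(qs)) < length(qs) || all(reference == reference[1L])) {
        if (all(reference == reference[1L])) {
            warning("constant reference: all regions in stratum 1")
            return(rep(1L, length(reference)))
        }
    }
    findInterval(reference, qs, left.open = TRUE) + 1L
}
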