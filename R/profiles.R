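#' Number of profile bins for a flank and bin width
#'
#' The smallest odd number of \code{binWidth}-bp bins whose total span
#' covers ±\code{flank} around a center: the center bin straddles the
#' midpoint and 98 bins extend to each side at the defaults (5 kb flank,
#' 51-bp bins: 197 bins spanning ±5023.5 bp).
#'
#' @param flank flank size in bp (default 5000).
#' @param binWidth bin width in bp (default 51).
#' @return odd integer bin count.
#' @export
profileBinCount <- function(flank = 5000, binWidth = 51) {
    2L * as.integer(ceiling((flank - binWidth / 2) / binWidth)) + 1L
}

#' Binned read-count matrix around region centers
#'
#' Counts read positions into \code{binWidth}-bp bins centered on each
#' region midpoint.  Offsets beyond the matrix span are dropped.  Bins that
#' would fall outside the chromosome (center closer than the span edge to a
#' chromosome end) are marked missing when chromosome lengths are supplied.
#'
#' @param readPositions data.frame with columns \code{chrom, pos} (0-based
#'   read start, or midpoint if precomputed).
#' @param centers data.frame with columns \code{chrom, center} (0-based
#'   positions) — typically tile midpoints.
#' @param flank flank in bp (default 5000).
#' @param binWidth bin width in bp (default 51).
#' @param chromSizes optional named vector of chromosome lengths for
#'   edge masking.
#' @return numeric matrix (regions x bins); column names are bin-center
#'   offsets in bp.
#' @export
profileMatrix <- function(readPositions, centers, flank = 5000,
                          binWidth = 51, chromSizes = NULL) {
    nb <- profileBinCount(flank, binWidth)
    half <- nb * binWidth / 2
    out <- matrix(0, nrow(centers), nb)
    colnames(out) <- (seq_len(nb) - (nb + 1) / 2) * binWidth
    for (ch in unique(centers$chrom)) {
        ci <- which(centers$chrom == ch)
        rp <- readPositions$pos[readPositions$chrom == ch]
        if (length(rp)) {
            rp <- sort(rp)
            for (i in ci) {
                off <- rp - centers$center[i]
                off <- off[off >= -half & off < half]
                if (length(off)) {
                    bin <- floor((off + half) / binWidth) + 1L
                    tb <- tabulate(bin, nbins = nb)
                    out[i, ] <- out[i, ] + tb
                }
            }
        }
        if (!is.null(chromSizes)) {
            len <- chromSizes[[ch]]
            for (i in ci) {
                ctr <- centers$center[i]
                binStart <- ctr - half + (seq_len(nb) - 1L) * binWidth
                bad <- binStart < 0 | (binStart + binWidth) > len
                out[i, bad] <- NA_real_
            }
        }
    }
    out
}

#' Running-mean smoothing of a profile matrix
#'
#' Each bin is replaced by the mean over the window of \code{halfwidth}
#' bins on each side plus the bin itself (21 bins at the default),
#' intersected with valid columns — edge windows and windows next to
#' missing bins shrink accordingly.
#'
#' @param m profile matrix (regions x bins).
#' @param halfwidth bins on each side (default 10); 0 is the identity.
#' @return smoothed matrix of the same shape.
#' @export
smoothProfile <- function(m, halfwidth = 10L) {
    stopifnot(halfwidth >= 0)
    if (halfwidth == 0L) return(m)
    nb <- ncol(m)
    out <- m
    for (j in seq_len(nb)) {
        w <- max(1L, j - halfwidth):min(nb, j + halfwidth)
        out[, j] <- rowMeans(m[, w, drop = FALSE], na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
}

#' Orient rows towards right-skewed signal
#'
#' Rows whose left half (excluding the center bin) carries more signal than
#' the right half are reversed, so the heavier tail always points right —
#' used for unstranded RNA tiles.  Ties are left unflipped; idempotent.
#'
#' @param m profile matrix with an odd number of columns.
#' @return matrix with rows oriented; attribute \code{"flipped"} marks the
#'   reversed rows.
#' @export
orientRowsBySignal <- function(m) {
    nb <- ncol(m)
    stopifnot(nb %% 2L == 1L)
    mid <- (nb + 1L) %/% 2L
    left <- rowSums(m[, seq_len(mid - 1L), drop = FALSE], na.rm = TRUE)
    right <- rowSums(m[, (mid + 1L):nb, drop = FALSE], na.rm = TRUE)
    flip <- left > right
    m[flip, ] <- m[flip, nb:1L, drop = FALSE]
    attr(m, "flipped") <- flip
    m
}

#' Per-group average profiles
#'
#' Column-wise means per group label; missing bins are excluded pairwise.
#'
#' @param m profile matrix (regions x bins).
#' @param groupLabels vector of labels covering all rows.
#' @return matrix (groups x bins) of mean signal.
#' @export
averageProfile <- function(m, groupLabels) {
    if (length(groupLabels) != nrow(m))
        stop("labels must cover all rows")
    if (anyNA(groupLabels)) stop("unknown (missing) group label")
    labs <- unique(groupLabels)
    out <- t(vapply(labs, function(g)
        colMeans(m[groupLabels == g, , drop = FALSE], na.rm = TRUE),
        numeric(ncol(m))))
    rownames(out) <- as.character(labs)
    out[is.nan(out)] <- NA_real_
    out
}
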