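#' GC class of a tile
#'
#' GC-rich means strictly more than 50 percent G+C; a tile at exactly the
#' cut-point is GC-poor. Missing GC gives \code{NA}.
#'
#' @param gcPercent numeric vector in [0, 100].
#' @param gcCut the cut-point (default 50).
#' @return factor with levels \code{GC-rich}, \code{GC-poor}.
#' @export
classifyGc <- function(gcPercent, gcCut = 50) {
    out <- ifelse(is.na(gcPercent), NA_character_,
                  ifelse(gcPercent > gcCut, "GC-rich", "GC-poor"))
    factor(out, levels = c("GC-rich", "GC-poor"))
}

#' Default cut-points of the hypoDMR trajectory decision table
#'
#' The six hypoDMR groups are defined by percent-methylation trajectories
#' across three states: prospermatogonia reference (psg), control sperm
#' (ctrl) and mutant sperm (dko). The published ranges are approximate
#' prose; this table fixes them numerically (every cut-point adjustable):
#' \itemize{
#'   \item groups 3/4: \code{psg < 20}, \code{25 <= ctrl <= 50},
#'     \code{dko < 5} — regions kept lowly methylated that collapse further;
#'   \item groups 1/2: \code{10 <= psg <= 50}, \code{ctrl > 50},
#'     \code{dko < 20} — bona fide de novo targets of adult spermatogenesis;
#'   \item groups 5/6: \code{30 <= psg <= 80}, \code{ctrl >= 75},
#'     \code{25 <= dko <= 75} — regions retaining mid-level methylation.
#' }
#' Rules are evaluated in the order 3/4, 1/2, 5/6 and the first match wins
#' (the sharp \code{dko} signature of 3/4 and 1/2 resolves box overlaps).
#' Odd group numbers are GC-rich, even GC-poor.
#'
#' @return A named list of cut-points.
#' @export
hypoDmrCutpoints <- function() {
    list(g34 = list(psg_max = 20, ctrl_min = 25, ctrl_max = 50, dko_max = 5),
         g12 = list(psg_min = 10, psg_max = 50, ctrl_min = 50, dko_max = 20),
         g56 = list(psg_min = 30, psg_max = 80, ctrl_min = 75,
                    dko_min = 25, dko_max = 75))
}

#' Assign hypoDMRs to the six trajectory groups
#'
#' Deterministic first-match classification of methylation trajectories (see
#' \code{\link{hypoDmrCutpoints}}). Tiles matching no box, or with any
#' missing input, are \code{"unclassified"}.
#'
#' @param mePsg,meCtrl,meDko percent methylation in the prospermatogonia
#'   reference, control sperm and mutant sperm (vectors, [0, 100]).
#' @param gcClass factor from \code{\link{classifyGc}} (or a gc_percent
#'   vector, classified on the fly).
#' @param cutpoints list as returned by \code{\link{hypoDmrCutpoints}}.
#' @return factor with levels \code{"1"..."6", "unclassified"}.
#' @export
classifyHypoDmr <- function(mePsg, meCtrl, meDko, gcClass,
                            cutpoints = hypoDmrCutpoints()) {
    if (is.numeric(gcClass)) gcClass <- classifyGc(gcClass)
    n <- length(mePsg)
    stopifnot(length(meCtrl) == n, length(meDko) == n, length(gcClass) == n)
    cp <- cutpoints
    pair <- rep(NA_integer_, n)
    ok <- !(is.na(mePsg) | is.na(meCtrl) | is.na(meDko) | is.na(gcClass))
    in34 <- ok & mePsg < cp$g34$psg_max &
        meCtrl >= cp$g34$ctrl_min & meCtrl <= cp$g34$ctrl_max &
        meDko < cp$g34$dko_max
    in12 <- ok & mePsg >= cp$g12$psg_min & mePsg <= cp$g12$psg_max &
        meCtrl > cp$g12$ctrl_min & meDko < cp$g12$dko_max
    in56 <- ok & mePsg >= cp$g56$psg_min & mePsg <= cp$g56$psg_max &
        meCtrl >= cp$g56$ctrl_min &
        meDko >= cp$g56$dko_min & meDko <= cp$g56$dko_max
    pair[in56] <- 5L
    pair[in12] <- 1L   # 1/2 overrides 5/6
    pair[in34] <- 3L   # 3/4 checked first: overrides both
    grp <- ifelse(is.na(pair), "unclassified",
                  as.character(pair + as.integer(gcClass == "GC-poor")))
    factor(grp, levels = c(as.character(1:6), "unclassified"))
}
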