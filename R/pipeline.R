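## round half-up (not banker's rounding) to `digits` decimals
round_half_up <- function(x, digits = 1L) {
    f <- 10^digits
    floor(x * f + 0.5) / f
}

#' Reporting summary of a DMR analysis
#'
#' Computes the headline percentages of a differential methylation run, as
#' reported in results text: the fraction of examined tiles that are
#' significant and the fraction of significant tiles that are
#' hypomethylated, both rounded half-up to one decimal.
#'
#' @param nExamined,nSignificant,nHypo,nHyper counts; alternatively pass a
#'   \code{\link{callDmrs}} result as \code{nExamined} and the rest are
#'   taken from its summary attribute.
#' @return list with the four counts plus \code{percent_significant} and
#'   \code{percent_hypo_of_significant} (NA when nothing is significant).
#' @examples
#' writeSummary(1944903, 20688, 20353, 335)
#' @export
writeSummary <- function(nExamined, nSignificant = NULL, nHypo = NULL,
                         nHyper = NULL) {
    if (is.data.frame(nExamined)) {
        s <- attr(nExamined, "summary")
        if (is.null(s)) stop("pass a callDmrs() result or explicit counts")
        nExamined <- s$n_examined; nSignificant <- s$n_significant
        nHypo <- s$n_hypo; nHyper <- s$n_hyper
    }
    list(n_examined = nExamined,
         n_significant = nSignificant,
         n_hypo = nHypo,
         n_hyper = nHyper,
         percent_significant =
             round_half_up(100 * nSignificant / nExamined, 1L),
         percent_hypo_of_significant =
             if (nSignificant == 0) NA_real_ else
                 round_half_up(100 * nHypo / nSignificant, 1L))
}

#' Run the simulated methylome-to-classification workflow end to end
#'
#' Generates a methylome with \code{\link{simulateMethylome}}, aggregates
#' CpG counts to tiles, applies the coverage/CpG filters, tests control
#' versus mutant, calls DMRs and classifies the hypoDMRs into trajectory
#' groups, returning every intermediate plus a machine-readable summary
#' with the thresholds echoed.  Deterministic given the config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param deltaThreshold,fdrThreshold DMR thresholds (defaults 25, 0.05).
#' @param minCpg,minReads tile filters (defaults 5, 25).
#' @return list with \code{sim, tm, records, classes, summary, provenance}.
#' @export
runPipeline <- function(config, deltaThreshold = 25, fdrThreshold = 0.05,
                        minCpg = 5L, minReads = 25L) {
    sim <- simulateMethylome(config)
    tm <- aggregateToTiles(sim$cpgs, sim$tiles)
    tm <- filterTiles(tm, minCpg = minCpg, minReads = minReads)
    ctrl <- sim$samples$sample_id[sim$samples$condition == "ctrl"]
    dko <- sim$samples$sample_id[sim$samples$condition == "dko"]
    psg <- sim$samples$sample_id[sim$samples$condition == "psg"]
    rec <- testDifferentialMethylation(tm, groupA = ctrl, groupB = dko)
    rec <- callDmrs(rec, deltaThreshold, fdrThreshold)
    mePsg <- percentMeth(tm[, psg], pooled = TRUE)
    meCtrl <- percentMeth(tm[, ctrl], pooled = TRUE)
    meDko <- percentMeth(tm[, dko], pooled = TRUE)
    gc <- rowRanges(tm)$gc_percent
    hypo <- rec$direction == "hypo"
    cls <- factor(rep(NA_character_, nrow(rec)),
                  levels = c(as.character(1:6), "unclassified"))
    cls[hypo] <- classifyHypoDmr(mePsg[hypo], meCtrl[hypo], meDko[hypo],
                                 classifyGc(gc[hypo]))
    classes <- data.frame(tile_id = rec$tile_id,
                          gc_class = classifyGc(gc),
                          group = cls, stringsAsFactors = FALSE)
    s <- writeSummary(rec)
    grp_counts <- table(cls[hypo])
    list(sim = sim, tm = tm, records = rec, classes = classes,
         summary = c(s, list(per_group = as.list(grp_counts))),
         provenance = list(seed = config$seed,
                           delta_threshold = deltaThreshold,
                           fdr_threshold = fdrThreshold,
                           min_cpg = minCpg, min_reads = minReads))
}
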