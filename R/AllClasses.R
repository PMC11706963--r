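#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   GRangesList
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb Seqinfo
NULL

#' TileMethylation: per-tile methylation counts across samples
#'
#' A \linkS4class{RangedSummarizedExperiment} holding, for a fixed set of
#' genomic tiles, the summed methylated (\code{"meth"}) and total
#' (\code{"total"}) CpG read counts per sample.  Percent methylation of a tile
#' in a sample is \code{100 * meth / total}; tiles with zero total coverage in
#' a sample have missing percent methylation.  Row ranges carry the tile
#' annotation produced by \code{\link{makeGenomeTiles}} /
#' \code{\link{annotateTiles}} (\code{tile_id}, \code{n_cpg},
#' \code{gc_percent}).
#'
#' @slot .. inherits all slots from RangedSummarizedExperiment.
#' @seealso \code{\link{aggregateToTiles}}, \code{\link{percentMeth}},
#'   \code{\link{testDifferentialMethylation}}
#' @export
setClass("TileMethylation", contains = "RangedSummarizedExperiment")

setValidity("TileMethylation", function(object) {
    msg <- character()
    if (!all(c("meth", "total") %in% assayNames(object)))
        msg <- c(msg, "assays must include 'meth' and 'total'")
    else {
        m <- assay(object, "meth")
        t <- assay(object, "total")
        if (any(m < 0, na.rm = TRUE) || any(t < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
        if (any(m > t, na.rm = TRUE))
            msg <- c(msg, "methylated counts cannot exceed totals")
    }
    if (is.null(rowRanges(object)$tile_id))
        msg <- c(msg, "rowRanges must carry a 'tile_id' column")
    if (length(msg)) msg else TRUE
})

#' TileOccupancy: per-tile chromatin read counts across samples
#'
#' A \linkS4class{SummarizedExperiment} with a \code{"counts"} assay of raw
#' reads per tile per sample, a per-sample \code{library_size} column in
#' \code{colData}, and the tile length (bp) in \code{metadata}.  After
#' \code{\link{normalizeOccupancy}} an additional \code{"log2rpkm"} assay
#' holds cyclic-loess normalized log2 RPKM, and
#' \code{metadata(x)$normalized} is \code{TRUE}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso \code{\link{log2Rpkm}}, \code{\link{cyclicLoessNormalize}},
#'   \code{\link{testDifferentialOccupancy}}
#' @export
setClass("TileOccupancy", contains = "SummarizedExperiment")

setValidity("TileOccupancy", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assays must include 'counts'")
    else if (any(assay(object, "counts") < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    ls <- colData(object)$library_size
    if (is.null(ls) || any(!is.finite(ls)) || any(ls <= 0))
        msg <- c(msg, "colData must carry positive 'library_size'")
    tl <- metadata(object)$tile_length
    if (is.null(tl) || tl <= 0)
        msg <- c(msg, "metadata must carry a positive 'tile_length'")
    if (length(msg)) msg else TRUE
})
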