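#' Construct a TileMethylation object
#'
#' @param meth,total integer matrices (tiles x samples) of methylated and
#'   total CpG read counts. Dimnames of \code{total} are used if \code{meth}
#'   has none.
#' @param tiles a \code{GRanges} of tiles (one per row) carrying at least a
#'   \code{tile_id} metadata column.
#' @param colData optional \code{DataFrame} of sample annotation.
#' @return A \linkS4class{TileMethylation}.
#' @export
TileMethylation <- function(meth, total, tiles, colData = NULL) {
    meth <- as.matrix(meth); total <- as.matrix(total)
    stopifnot(identical(dim(meth), dim(total)),
              length(tiles) == nrow(meth))
    if (is.null(colnames(total)))
        colnames(total) <- colnames(meth) <- paste0("S", seq_len(ncol(total)))
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(total))
    new("TileMethylation", SummarizedExperiment(
        assays = list(meth = meth, total = total),
        rowRanges = tiles, colData = colData))
}

#' Construct a TileOccupancy object
#'
#' @param counts integer matrix (tiles x samples) of reads overlapping each
#'   tile.
#' @param librarySize numeric vector of per-sample total mapped (or allelic)
#'   reads; defaults to the column sums of \code{counts}.
#' @param tileLength tile width in bp used for RPKM (default 500).
#' @param tiles optional \code{GRanges} of tiles; plain row names are kept
#'   otherwise.
#' @return A \linkS4class{TileOccupancy}.
#' @export
TileOccupancy <- function(counts, librarySize = colSums(counts),
                          tileLength = 500, tiles = NULL) {
    counts <- as.matrix(counts)
    cd <- DataFrame(library_size = as.numeric(librarySize),
                    row.names = colnames(counts))
    se <- if (is.null(tiles)) {
        SummarizedExperiment(assays = list(counts = counts), colData = cd)
    } else {
        SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = tiles, colData = cd)
    }
    metadata(se)$tile_length <- tileLength
    metadata(se)$normalized <- FALSE
    new("TileOccupancy", se)
}

#' @rdname TileMethylation
#' @param x a \code{TileMethylation}.
#' @export
methCounts <- function(x) assay(x, "meth")

#' @rdname TileMethylation
#' @export
totalCounts <- function(x) assay(x, "total")

#' Percent methylation per tile and sample
#'
#' \code{100 * meth / total}; \code{NA} where a tile has no coverage in a
#' sample.
#'
#' @param x a \code{TileMethylation}.
#' @param pooled if \code{TRUE}, sum counts across samples first and return a
#'   single vector (the replicate-pooled percent methylation used for DMR
#'   effect sizes and group classification).
#' @return A matrix (or vector when \code{pooled}) of percentages in [0,100].
#' @export
percentMeth <- function(x, pooled = FALSE) {
    m <- assay(x, "meth"); t <- assay(x, "total")
    if (pooled) {
        ms <- rowSums(m); ts <- rowSums(t)
        return(ifelse(ts > 0, 100 * ms / ts, NA_real_))
    }
    p <- 100 * m / t
    p[t == 0] <- NA_real_
    p
}

#' @rdname TileOccupancy
#' @param x a \code{TileOccupancy}.
#' @export
occupancyCounts <- function(x) assay(x, "counts")

#' @rdname TileOccupancy
#' @export
librarySizes <- function(x) colData(x)$library_size

setMethod("show", "TileMethylation", function(object) {
    cat(sprintf("TileMethylation: %d tiles x %d samples\n",
                nrow(object), ncol(object)))
    t <- assay(object, "total")
    cat(sprintf("  median tile coverage per sample: %.0f reads\n",
                stats::median(t)))
    cov <- colnames(object)
    if (length(cov)) cat("  samples:", paste(cov, collapse = ", "), "\n")
})

setMethod("show", "TileOccupancy", function(object) {
    cat(sprintf("TileOccupancy: %d tiles x %d samples (tile length %d bp)\n",
                nrow(object), ncol(object), metadata(object)$tile_length))
    cat(sprintf("  normalized: %s\n", isTRUE(metadata(object)$normalized)))
})
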