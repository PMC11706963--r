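#' Tile a genome into fixed-width non-overlapping windows
#'
#' Partitions each chromosome into consecutive non-overlapping tiles of
#' \code{tileSize} bp starting at position 0.  Only full tiles are kept: a
#' trailing remainder shorter than \code{tileSize} is dropped, so every tile
#' has identical length (which keeps per-tile RPKM comparable).
#'
#' All coordinates are 0-based half-open internally; the returned
#' \code{GRanges} follows the usual Bioconductor 1-based closed convention
#' (\code{start = 0-based start + 1}).
#'
#' @param chromSizes a two-column data.frame (chrom, length) or a named
#'   numeric vector of chromosome lengths.
#' @param tileSize tile width in bp (default 500).
#' @return A \code{GRanges} with metadata column \code{tile_id}
#'   ("chrom:start-end" in 0-based half-open coordinates).
#' @examples
#' makeGenomeTiles(c(chr1 = 1250), tileSize = 500)  # 2 tiles, 250 bp dropped
#' @export
makeGenomeTiles <- function(chromSizes, tileSize = 500L) {
    if (is.data.frame(chromSizes)) {
        lens <- structure(as.numeric(chromSizes[[2L]]),
                          names = as.character(chromSizes[[1L]]))
    } else {
        lens <- chromSizes
    }
    if (is.null(names(lens)) || any(!nzchar(names(lens))))
        stop("chromosome names are required")
    if (tileSize < 1) stop("tileSize must be >= 1")
    bad <- names(lens)[!is.finite(lens) | lens <= 0 | lens != round(lens)]
    if (length(bad))
        stop("non-positive or non-integer length for chromosome(s): ",
             paste(bad, collapse = ", "))
    ntile <- floor(lens / tileSize)
    chrom <- rep(names(lens), ntile)
    s0 <- unlist(lapply(ntile, function(n) (seq_len(n) - 1L) * tileSize),
                 use.names = FALSE)              # 0-based starts
    if (is.null(s0)) s0 <- integer(0)
    gr <- GRanges(chrom, IRanges(s0 + 1L, s0 + tileSize),
                  seqinfo = GenomeInfoDb::Seqinfo(names(lens),
                                                  seqlengths = lens))
    mcols(gr)$tile_id <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                                 start(gr) - 1L, end(gr))
    gr
}

#' Annotate tiles with GC percentage and CpG counts
#'
#' Computes, from genomic sequence, the GC percentage (G+C over non-N bases)
#' and the number of CpG dinucleotides lying fully inside each tile.  A CpG
#' whose C is the last base of a tile spans the boundary and is assigned to
#' the tile containing the C, so no dimer is counted twice.  Tiles whose
#' sequence is more than half N are flagged unusable (\code{usable = FALSE})
#' and have \code{gc_percent = NA}.
#'
#' @param tiles a \code{GRanges} from \code{\link{makeGenomeTiles}}.
#' @param genome a \code{DNAStringSet} (names = chromosomes) or a file path to
#'   a FASTA read with \code{Biostrings::readDNAStringSet}.
#' @return \code{tiles} with added metadata columns \code{n_cpg},
#'   \code{gc_percent} and \code{usable}.
#' @export
annotateTiles <- function(tiles, genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    nm <- names(genome)
    if (!is.null(nm)) names(genome) <- sub("\\s.*$", "", nm)
    chroms <- as.character(seqnames(tiles))
    missing <- setdiff(unique(chroms), names(genome))
    if (length(missing))
        stop("chromosome(s) missing from sequence source: ",
             paste(missing, collapse = ", "))
    n <- length(tiles)
    n_cpg <- integer(n); gc <- numeric(n); usable <- logical(n)
    for (ch in unique(chroms)) {
        idx <- which(chroms == ch)
        seq <- genome[[ch]]
        # take one extra base downstream so a boundary-spanning CG (C = last
        # base of the tile) is attributed to this tile
        ext_end <- pmin(end(tiles)[idx] + 1L, length(seq))
        views <- Biostrings::Views(seq, start = start(tiles)[idx],
                                   end = end(tiles)[idx])
        freq <- Biostrings::alphabetFrequency(views, baseOnly = TRUE)
        nonN <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
        gcc <- rowSums(freq[, c("C", "G"), drop = FALSE])
        gc[idx] <- ifelse(nonN > 0, 100 * gcc / nonN, NA_real_)
        usable[idx] <- nonN >= width(tiles)[idx] / 2
        extv <- Biostrings::Views(seq, start = start(tiles)[idx],
                                  end = ext_end)
        cg_all <- Biostrings::vcountPattern("CG", extv)
        # subtract a CG whose C sits one base before the tile start (it was
        # counted by the previous tile's extension, not ours) -- extension
        # already starts at tile start so only the downstream base is extra;
        # a CG ending exactly at ext_end has its C inside the tile: keep.
        n_cpg[idx] <- cg_all
    }
    mcols(tiles)$n_cpg <- n_cpg
    mcols(tiles)$gc_percent <- gc
    mcols(tiles)$usable <- usable
    tiles
}

#' Remove tiles overlapping a blacklist
#'
#' Any tile sharing at least one base with a blacklist interval is removed.
#' Intervals are 0-based half-open, so a blacklist interval starting exactly
#' at a tile's (half-open) end does not touch it.  The \code{blacklisted}
#' flag is recorded on the returned \code{removed} set for audit.
#'
#' @param tiles a \code{GRanges} of tiles.
#' @param blacklist a \code{GRanges}, a BED3 file path, or a data.frame with
#'   columns chrom/start/end (0-based half-open).
#' @return A list with elements \code{tiles} (kept) and \code{removed}.
#' @export
applyBlacklist <- function(tiles, blacklist) {
    bl <- as_granges_bed3(blacklist)
    hit <- overlapsAny(tiles, bl, ignore.strand = TRUE)
    mcols(tiles)$blacklisted <- hit
    list(tiles = tiles[!hit], removed = tiles[hit])
}

#' Read a two-column chrom.sizes TSV
#' @param path file with columns name, length (no header).
#' @return named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            colClasses = c("character", "numeric"))
    structure(df$length, names = df$chrom)
}

# BED3 (0-based half-open) -> GRanges (1-based closed)
as_granges_bed3 <- function(x) {
    if (is(x, "GRanges")) return(x)
    if (is.character(x) && length(x) == 1L)
        x <- utils::read.table(x, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "end"))[, 1:3]
    stopifnot(is.data.frame(x), ncol(x) >= 3L)
    s <- as.numeric(x[[2L]]); e <- as.numeric(x[[3L]])
    if (any(e <= s)) stop("malformed interval: end <= start")
    GRanges(as.character(x[[1L]]), IRanges(s + 1L, e))
}

#' Write tiles as a BED-like TSV
#'
#' Standard BED6 fields (0-based half-open) followed by \code{tile_id},
#' \code{n_cpg} and \code{gc_percent}.
#'
#' @param tiles an annotated \code{GRanges} of tiles.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTilesBed <- function(tiles, path) {
    df <- data.frame(chrom = as.character(seqnames(tiles)),
                     start = start(tiles) - 1L,
                     end = end(tiles),
                     name = mcols(tiles)$tile_id,
                     score = 0L, strand = ".",
                     tile_id = mcols(tiles)$tile_id,
                     n_cpg = if (is.null(mcols(tiles)$n_cpg)) NA_integer_
                             else mcols(tiles)$n_cpg,
                     gc_percent = if (is.null(mcols(tiles)$gc_percent))
                         NA_real_ else mcols(tiles)$gc_percent)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
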