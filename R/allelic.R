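#' Read a SNP table for a hybrid cross
#'
#' TSV with columns \code{chrom, pos, base_ref, base_alt}; positions 0-based.
#' Only biallelic single-nucleotide records are accepted and (chrom, pos)
#' must be unique.
#'
#' @param path file path or equivalent data.frame.
#' @param oneBased set \code{TRUE} if positions are 1-based.
#' @return data.frame with the four typed columns, 0-based positions.
#' @export
readSnpTable <- function(path, oneBased = FALSE) {
    df <- if (is.data.frame(path)) path else {
        first <- readLines(path, n = 1L)
        utils::read.table(path, sep = "\t",
                          header = grepl("chrom", first, fixed = TRUE),
                          stringsAsFactors = FALSE)
    }
    names(df)[1:4] <- c("chrom", "pos", "base_ref", "base_alt")
    if (oneBased) df$pos <- df$pos - 1L
    if (any(nchar(df$base_ref) != 1L | nchar(df$base_alt) != 1L))
        stop("only single-nucleotide SNPs are supported")
    if (any(df$base_ref == df$base_alt))
        stop("base_ref must differ from base_alt")
    if (anyDuplicated(df[, c("chrom", "pos")]))
        stop("duplicated (chrom, pos) in SNP table")
    df
}

#' Count allelic mismatches of aligned reads at SNP positions
#'
#' For each read (indel-free alignment: read base i sits at reference
#' position \code{pos + i - 1}), every overlapped SNP is compared with the
#' read base: a match to the maternal base adds one mismatch against the
#' paternal haplotype, a match to the paternal base adds one against the
#' maternal haplotype, and a third base adds one to both.  Non-SNP positions
#' are ignored, which gives the same maternal/paternal calls as comparing
#' full alignments against the two SNP-substituted genomes.
#'
#' @param reads data.frame with columns \code{read_id, chrom, pos, seq}
#'   (0-based alignment start).
#' @param snps data.frame from \code{\link{readSnpTable}}.
#' @param altIsMaternal which strain carries \code{base_alt}: \code{TRUE}
#'   (default) when the alternate-strain base is the maternal one (e.g. a
#'   JF1 dam on an mm10/C57BL6 reference).
#' @return data.frame with \code{read_id, n_snps, mm_mat, mm_pat, call}.
#' @export
countAllelicMismatches <- function(reads, snps, altIsMaternal = TRUE) {
    n <- nrow(reads)
    mm_mat <- integer(n); mm_pat <- integer(n); n_snps <- integer(n)
    snp_key <- split(seq_len(nrow(snps)), snps$chrom)
    for (ch in unique(reads$chrom)) {
        ridx <- which(reads$chrom == ch)
        sidx <- snp_key[[ch]]
        if (is.null(sidx)) next
        spos <- snps$pos[sidx]
        for (k in ridx) {
            start <- reads$pos[k]
            len <- nchar(reads$seq[k])
            ov <- sidx[spos >= start & spos < start + len]
            if (!length(ov)) next
            off <- snps$pos[ov] - start + 1L
            base <- substring(reads$seq[k], off, off)
            matBase <- if (altIsMaternal) snps$base_alt[ov] else
                snps$base_ref[ov]
            patBase <- if (altIsMaternal) snps$base_ref[ov] else
                snps$base_alt[ov]
            n_snps[k] <- length(ov)
            mm_pat[k] <- sum(base == matBase) + sum(base != matBase &
                                                    base != patBase)
            mm_mat[k] <- sum(base == patBase) + sum(base != matBase &
                                                    base != patBase)
        }
    }
    data.frame(read_id = reads$read_id, n_snps = n_snps,
               mm_mat = mm_mat, mm_pat = mm_pat,
               call = assignAllele(mm_mat, mm_pat),
               stringsAsFactors = FALSE)
}

#' Assign a read to the maternal or paternal genome
#'
#' Minimal-mismatch rule: \code{maternal} when \code{mm_mat < mm_pat},
#' \code{paternal} when \code{mm_pat < mm_mat}, \code{undefined} on a tie
#' (including reads overlapping no informative SNP, where both are 0).
#'
#' @param mmMat,mmPat non-negative integer vectors of mismatches against
#'   the maternal / paternal haplotype.
#' @return factor with levels \code{maternal, paternal, undefined}.
#' @export
assignAllele <- function(mmMat, mmPat) {
    stopifnot(all(mmMat >= 0), all(mmPat >= 0))
    out <- ifelse(mmMat < mmPat, "maternal",
                  ifelse(mmPat < mmMat, "paternal", "undefined"))
    factor(out, levels = c("maternal", "paternal", "undefined"))
}

#' Allelic library sizes
#'
#' Counts of maternal and paternal read calls; undefined reads are excluded.
#' These feed \code{\link{log2Rpkm}} as library sizes in allelic mode.
#'
#' @param assignments data.frame with a \code{call} column (or the factor
#'   itself).
#' @return named integer vector \code{c(maternal = , paternal = )}.
#' @export
allelicLibrarySizes <- function(assignments) {
    call <- if (is.data.frame(assignments)) assignments$call else assignments
    c(maternal = sum(call == "maternal"),
      paternal = sum(call == "paternal"))
}

#' Allelic calls from a dual-alignment mismatch table
#'
#' Adapter for pipelines that align each read to both SNP-substituted
#' genomes and record total mismatch counts: the minimal-mismatch rule is
#' applied to the two columns directly.
#'
#' @param readId read identifiers.
#' @param mmMaternalAln,mmPaternalAln total mismatches of the alignment to
#'   the maternal / paternal genome.
#' @return data.frame with \code{read_id, mm_mat, mm_pat, call}.
#' @export
assignAlleleDual <- function(readId, mmMaternalAln, mmPaternalAln) {
    data.frame(read_id = readId, mm_mat = mmMaternalAln,
               mm_pat = mmPaternalAln,
               call = assignAllele(mmMaternalAln, mmPaternalAln),
               stringsAsFactors = FALSE)
}
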