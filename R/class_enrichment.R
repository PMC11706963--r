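#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact p by hypergeometric summation over all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (the "sum of tables no more probable" two-sided convention; one-sided
#' alternatives sum one tail).
#'
#' @param tab 2x2 integer matrix \code{rbind(c(a, b), c(c, d))}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"} (on the [1,1] cell).
#' @return the p-value.
#' @export
fisherExactP <- function(tab, alternative = c("two.sided", "greater",
                                              "less")) {
    alternative <- match.arg(alternative)
    stopifnot(all(dim(tab) == 2L), all(tab >= 0))
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0L, k - n); hi <- min(k, m)
    x <- lo:hi
    d <- stats::dhyper(x, m, n, k)
    switch(alternative,
           two.sided = sum(d[d <= d[x == a] * (1 + 1e-7)]),
           greater = sum(d[x >= a]),
           less = sum(d[x <= a]))
}

#' Class-enrichment test over a tile universe
#'
#' Builds the 2x2 table of class membership against significance, computes
#' the two-sided Fisher exact p, the sample odds ratio, and the
#' log2 observed/expected enrichment with pseudocount 1 (see
#' \code{\link{log2ObsExp}}).  Degenerate margins (a class or outcome
#' entirely absent) give \code{p = 1} with \code{degenerate = TRUE}.
#'
#' @param membership logical vector: tile belongs to the class.
#' @param significant logical vector: tile significantly changed.
#' @param alternative passed to \code{\link{fisherExactP}}.
#' @return list with \code{table} (2x2), \code{observed}, \code{expected},
#'   \code{log2_oe}, \code{fisher_p}, \code{odds_ratio}, \code{degenerate}.
#' @export
fisherEnrichment <- function(membership, significant,
                             alternative = "two.sided") {
    stopifnot(length(membership) == length(significant))
    ok <- !(is.na(membership) | is.na(significant))
    membership <- membership[ok]; significant <- significant[ok]
    a <- sum(membership & significant)
    b <- sum(membership & !significant)
    c <- sum(!membership & significant)
    d <- sum(!membership & !significant)
    tab <- matrix(c(a, c, b, d), 2L, 2L,
                  dimnames = list(class = c("in", "out"),
                                  sig = c("yes", "no")))
    N <- a + b + c + d
    expected <- (a + b) * (a + c) / N
    degenerate <- (a + b) == 0 || (c + d) == 0 || (a + c) == 0 ||
        (b + d) == 0
    p <- if (degenerate) 1 else fisherExactP(tab, alternative)
    or <- if (b == 0 || c == 0 || a == 0 || d == 0) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))  # Haldane
    } else (a * d) / (b * c)
    list(table = tab, observed = a, expected = expected,
         log2_oe = log2((a + 1) / (expected + 1)),
         fisher_p = p, odds_ratio = or,
         haldane = b == 0 || c == 0 || a == 0 || d == 0,
         degenerate = degenerate)
}

#' log2 observed/expected enrichment of a 2x2 table
#'
#' Expected count of the [1,1] cell from the table margins
#' (\code{row1 * col1 / N}); returns
#' \code{log2((observed + 1) / (expected + 1))}.
#'
#' @param tab 2x2 matrix of counts.
#' @return the log2 enrichment.
#' @export
log2ObsExp <- function(tab) {
    stopifnot(all(dim(tab) == 2L))
    N <- sum(tab)
    expected <- sum(tab[1, ]) * sum(tab[, 1]) / N
    log2((tab[1, 1] + 1) / (expected + 1))
}
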