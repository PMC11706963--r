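# Independent oracles used across the suite.  These are deliberately naive
# (enumeration / closed form) and never call the implementation they check.

# brute-force BH step-up: sort, p*(m/rank), cumulative min from the top
bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
    pmin(adj, 1)[order(o)]
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins via log-factorial products (no dhyper)
fisher_oracle <- function(a, b, c, d) {
    lfact <- function(x) lgamma(x + 1)
    m <- a + b; n <- c + d; k <- a + c; N <- m + n
    prob <- function(x) exp(lfact(m) + lfact(n) + lfact(k) + lfact(N - k) -
                            lfact(N) - lfact(x) - lfact(m - x) -
                            lfact(k - x) - lfact(n - k + x))
    xs <- max(0, k - n):min(k, m)
    ps <- vapply(xs, prob, numeric(1))
    sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# closed-form binomial likelihood-ratio test for two groups of (m, t)
binom_lrt_oracle <- function(mA, tA, mB, tB) {
    ll <- function(m, t, p) sum(dbinom(m, t, min(max(p, 1e-12), 1 - 1e-12),
                                       log = TRUE))
    p0 <- sum(mA, mB) / sum(tA, tB)
    pA <- sum(mA) / sum(tA); pB <- sum(mB) / sum(tB)
    lrt <- 2 * (ll(mA, tA, pA) + ll(mB, tB, pB) -
                ll(c(mA, mB), c(tA, tB), p0))
    pchisq(max(0, lrt), df = 1, lower.tail = FALSE)
}

# beta-binomial sampler for fixtures (independent of the package internals)
rbb <- function(n, size, p, phi) {
    if (phi <= 0) return(rbinom(n, size, p))
    a <- p * (1 - phi) / phi
    b <- (1 - p) * (1 - phi) / phi
    rbinom(n, size, rbeta(n, a, b))
}

# build a small TileMethylation from count matrices
make_tm <- function(m, t, n_cpg = 10L) {
    tiles <- makeGenomeTiles(c(chrT = nrow(m) * 500L))
    S4Vectors::mcols(tiles)$n_cpg <- n_cpg
    TileMethylation(m, t, tiles)
}
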