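# Independent oracles used to cross-check the package's implementations.
# Each is written as plain, slow, obviously-correct code and never shares
# a code path with the function it checks.

# Brute-force R statistic: explicit loop over libraries.
rStatBrute <- function(x, N) {
    p <- sum(x) / sum(N)
    R <- 0
    for (j in seq_along(x)) {
        if (x[j] > 0) R <- R + x[j] * log(x[j] / (N[j] * p))
    }
    R
}

# Exhaustive rarefaction: enumerate every without-replacement subsample
# of size m from the expanded multiset and average the distinct-TU count.
rarefyEnum <- function(counts, m) {
    pool <- rep(seq_along(counts), counts)
    subs <- utils::combn(length(pool), m)
    mean(apply(subs, 2L, function(idx) length(unique(pool[idx]))))
}

# Monte-Carlo rarefaction: mean and standard error over draws.
rarefyMC <- function(counts, m, nDraws = 10000) {
    pool <- rep(seq_along(counts), counts)
    s <- replicate(nDraws, length(unique(sample(pool, m))))
    list(mean = mean(s), se = stats::sd(s) / sqrt(nDraws))
}

# Exhaustive hypergeometric upper tail via explicit choose() sums.
hyperUpperBrute <- function(k, K, N, n) {
    # P(X >= k), X = #marked in a draw of n from N with K marked
    kk <- max(k, max(0, n - (N - K))):min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Independent CA inertia oracle: eigen-decomposition of the chi-square
# residual cross-product, built with explicit loops.
caInertiaOracle <- function(m) {
    tot <- sum(m)
    P <- m / tot
    r <- rowSums(P); cc <- colSums(P)
    S <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
        for (j in seq_len(ncol(m)))
            S[i, j] <- (P[i, j] - r[i] * cc[j]) / sqrt(r[i] * cc[j])
    ev <- eigen(t(S) %*% S, symmetric = TRUE)$values
    ev[ev < 0] <- 0
    sort(ev, decreasing = TRUE)
}

# Small random count matrix with no all-zero rows.
randomCountMatrix <- function(nTU, nLib, lambda = 2) {
    repeat {
        m <- matrix(rpois(nTU * nLib, lambda), nTU, nLib,
                    dimnames = list(sprintf("T%03d", seq_len(nTU)),
                                    sprintf("L%02d", seq_len(nLib))))
        if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
    }
}
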