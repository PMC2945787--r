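#' Analytic rarefaction of one library
#'
#' Expected number of distinct TUs in a without-replacement subsample of
#' size m from a library, computed analytically from the hypergeometric
#' expectation
#' \deqn{E[S_m] = \sum_i \left(1 - \binom{N - n_i}{m} / \binom{N}{m}\right)}
#' where n_i are the per-TU counts and N their total. Binomial-coefficient
#' ratios are evaluated in log space, so large libraries are handled
#' without overflow. A library is "below saturation" when the curve is
#' still rising at m = N.
#'
#' @param counts nonnegative per-TU counts for one library (zeros allowed
#'   and ignored); total must be at least 1.
#' @param m subsample sizes, each in `1..sum(counts)`. Default: 20 evenly
#'   spaced sizes from 1 to N.
#' @return data.frame with columns `m` and `expected_richness`.
#' @examples
#' rarefy(c(2, 1), m = 1:3)
#' @export
rarefy <- function(counts, m = NULL) {
    if (any(counts < 0) || anyNA(counts))
        stop("counts must be nonnegative")
    n <- counts[counts > 0]
    N <- sum(n)
    if (N < 1) stop("library is empty")
    if (is.null(m))
        m <- unique(round(seq(1, N, length.out = min(20L, N))))
    if (any(m < 1) || any(m > N))
        stop(sprintf("subsample size must lie in 1..%d", N))
    er <- vapply(m, function(mm) {
        # lchoose(N - n_i, mm) is -Inf when mm > N - n_i: that TU is
        # certain to appear, and the ratio term is 0.
        sum(1 - exp(lchoose(N - n, mm) - lchoose(N, mm)))
    }, numeric(1))
    data.frame(m = m, expected_richness = er)
}

#' Rarefaction curves for every library
#'
#' @param x an [ESTCountSet-class].
#' @param nPoints number of evenly spaced subsample sizes per library.
#' @return data.frame with columns `library_id`, `m`, `expected_richness`.
#' @export
rarefactionCurves <- function(x, nPoints = 20L) {
    m <- estCounts(x)
    out <- lapply(colnames(m), function(lib) {
        N <- sum(m[, lib])
        grid <- unique(round(seq(1, N, length.out = min(nPoints, N))))
        cbind(library_id = lib, rarefy(m[, lib], grid))
    })
    do.call(rbind, out)
}

#' Simpson's index and its reciprocal for one library
#'
#' Computes \eqn{D = \sum_i n_i (n_i - 1) / (N (N - 1))}, the probability
#' that two cDNAs drawn without replacement belong to the same TU, and its
#' reciprocal 1/D (Simpson's Reciprocal Index; higher means a more
#' diverse, more even library). When every TU is a singleton D = 0 and the
#' reciprocal is undefined: it is reported as `NA` with `undefined = TRUE`
#' rather than infinity, so non-finite values never propagate into tables.
#'
#' @param counts nonnegative per-TU counts for one library; N >= 2.
#' @return list with elements `D`, `reciprocal`, `undefined`, `N`, `n_tus`.
#' @examples
#' simpsonIndex(c(5, 3, 2))  # D = 28/90
#' @export
simpsonIndex <- function(counts) {
    n <- counts[counts > 0]
    N <- sum(n)
    if (N < 2) stop("Simpson undefined: library size below 2")
    D <- sum(n * (n - 1)) / (N * (N - 1))
    list(D = D,
         reciprocal = if (D > 0) 1 / D else NA_real_,
         undefined = D == 0,
         N = N, n_tus = length(n))
}

#' Per-library diversity summary
#'
#' Applies [simpsonIndex()] to every library of a count set.
#'
#' @param x an [ESTCountSet-class].
#' @return a [S4Vectors::DataFrame] with columns `library_id`, `N`,
#'   `richness`, `D`, `reciprocal`, `undefined`.
#' @export
libraryDiversity <- function(x) {
    m <- estCounts(x)
    res <- lapply(colnames(m), function(lib) {
        s <- simpsonIndex(m[, lib])
        DataFrame(library_id = lib, N = s$N, richness = s$n_tus,
                  D = s$D, reciprocal = s$reciprocal,
                  undefined = s$undefined)
    })
    out <- do.call(rbind, res)
    rownames(out) <- out$library_id
    out
}
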