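#' Log-likelihood R statistic for one TU
#'
#' For counts x_j of one TU across libraries of sizes N_j, the omnibus
#' statistic
#' \deqn{R = \sum_j x_j \ln\left(\frac{x_j}{N_j p}\right), \quad
#'       p = \frac{\sum_j x_j}{\sum_j N_j}}
#' (natural logarithm; 0 ln 0 = 0) measures the departure of the observed
#' per-library counts from a single shared frequency p. R = 0 exactly
#' when every library's frequency equals p; large R indicates
#' differential representation across libraries. N_j p is the expected
#' cluster size of the TU in library j under the shared-frequency model.
#'
#' @param x nonnegative counts, one per library; at least one positive.
#' @param N positive library sizes, same length as `x`.
#' @return list with elements `R`, `expected` (the per-library N_j p) and
#'   `p` (the pooled frequency).
#' @examples
#' rStatistic(c(10, 0), c(100, 100))$R  # 10 * log(2)
#' @export
rStatistic <- function(x, N) {
    if (length(x) != length(N))
        stop("x and N must have the same length")
    if (length(x) < 2L)
        stop("at least two libraries are required")
    if (any(N <= 0)) stop("library sizes must be positive")
    if (any(x < 0)) stop("counts must be nonnegative")
    if (sum(x) < 1) stop("all-zero count vector")
    p <- sum(x) / sum(N)
    lam <- N * p
    pos <- x > 0
    R <- sum(x[pos] * log(x[pos] / lam[pos]))
    list(R = R, expected = lam, p = p)
}

# Vectorized R over the rows of a count matrix. Returns the R vector;
# lambda (n x L matrix of expected cluster sizes) as attribute when asked.
.rValuesMatrix <- function(m, N = colSums(m)) {
    p <- rowSums(m) / sum(N)
    lam <- outer(p, N)
    term <- m * log(m / lam)
    term[m == 0] <- 0
    rowSums(term)
}

#' R values for every TU of a count set
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @return named numeric vector of R values (natural-log units), one per
#'   TU, in row order.
#' @seealso [rStatistic()] for the definition, [calibrateCutoff()] for
#'   choosing a significance cutoff.
#' @export
rValues <- function(x) {
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    r <- .rValuesMatrix(m)
    names(r) <- rownames(m)
    r
}

#' Calibrate the R-value cutoff by Poisson randomization
#'
#' Draws `nReplicates` null datasets in which each TU's count in library
#' j is Poisson with mean equal to its expected cluster size N_j p_i
#' (p_i the TU's pooled frequency), recomputes R for every null cluster,
#' and returns the empirical `quantileTarget` quantile of the pooled null
#' R distribution as the cutoff. Null draws that are all-zero across
#' libraries are redrawn (an R value requires a nonempty cluster, as all
#' observed clusters are). The largest null R is recorded: beyond it,
#' null exceedance was never observed.
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @param nReplicates number of whole-matrix null replicates (default 1000).
#' @param quantileTarget quantile of the pooled null distribution used as
#'   cutoff (default 0.96: 96% chance a flagged TU is not a random event).
#' @param seed optional integer seed; identical seeds and inputs
#'   reproduce the calibration exactly.
#' @param keepNull keep the pooled null R values in the result (needed
#'   for exceedance diagnostics; default TRUE).
#' @return a [NullCalibration-class].
#' @export
calibrateCutoff <- function(x, nReplicates = 1000L, quantileTarget = 0.96,
                            seed = NULL, keepNull = TRUE) {
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    if (ncol(m) < 2L)
        stop("calibration needs at least two libraries")
    if (nReplicates < 1L) stop("nReplicates must be >= 1")
    if (quantileTarget <= 0 || quantileTarget >= 1)
        stop("quantileTarget must lie in (0, 1)")
    if (!is.null(seed)) set.seed(seed)
    N <- colSums(m)
    p <- rowSums(m) / sum(N)
    lam <- outer(p, N)
    n <- nrow(m); L <- ncol(m)
    nullR <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        xs <- matrix(stats::rpois(n * L, lam), n, L)
        empty <- which(rowSums(xs) == 0)
        while (length(empty)) {
            xs[empty, ] <- stats::rpois(length(empty) * L, lam[empty, ])
            empty <- empty[rowSums(xs[empty, , drop = FALSE]) == 0]
        }
        nullR[[r]] <- .rValuesMatrix(xs, N)
    }
    nullR <- unlist(nullR, use.names = FALSE)
    cutoff <- unname(stats::quantile(nullR, quantileTarget, names = FALSE))
    new("NullCalibration",
        cutoff = cutoff, maxNullR = max(nullR),
        nullR = if (keepNull) nullR else numeric(0),
        nReplicates = as.integer(nReplicates),
        quantileTarget = quantileTarget,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname NullCalibration-class
#' @export
setMethod("cutoffValue", "NullCalibration", function(x) x@cutoff)

#' @rdname NullCalibration-class
#' @export
setMethod("maxNullR", "NullCalibration", function(x) x@maxNullR)

#' @rdname NullCalibration-class
#' @export
setMethod("nullRValues", "NullCalibration", function(x) x@nullR)

#' @rdname NullCalibration-class
#' @export
setMethod("show", "NullCalibration", function(object) {
    cat(sprintf(
        "NullCalibration: cutoff %.3f at quantile %.3f (%d replicates%s)\n",
        object@cutoff, object@quantileTarget, object@nReplicates,
        if (is.na(object@seed)) "" else sprintf(", seed %d", object@seed)))
    cat(sprintf("  max null R: %.3f; %s null values %s\n", object@maxNullR,
        format(length(object@nullR), big.mark = ","),
        if (length(object@nullR)) "retained" else "discarded"))
})

#' Catalogue differentially expressed TUs
#'
#' Applies the R cutoff to every TU and assigns each differentially
#' expressed TU to the libraries where its frequency is highest. TUs
#' represented by three or fewer cDNAs in total are removed from
#' consideration (`filtered_low_count`); remaining TUs with R at or above
#' the cutoff are catalogued as differentially expressed in the (up to
#' two) libraries with the highest frequencies. Frequency ties are broken
#' by library column order; libraries where the TU is absent are never
#' assigned, so a TU observed in a single library is assigned to that
#' library alone.
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @param cutoff positive R cutoff, typically
#'   `cutoffValue(calibrateCutoff(x))` or the fixed reference value 12
#'   (natural-log units).
#' @param minTotal row totals at or below `minTotal - 1`... the filter:
#'   TUs with total count `<= minTotal` are never called (default 3).
#' @return a [S4Vectors::DataFrame] with one row per TU: `tu_id`, `R`,
#'   `total`, `filtered_low_count`, `is_de`, and `assigned` (a
#'   [IRanges::CharacterList] of 0-2 library ids, nonempty only for DE
#'   TUs).
#' @export
catalogueDifferential <- function(x, cutoff, minTotal = 3L) {
    if (cutoff <= 0) stop("cutoff must be positive")
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    R <- .rValuesMatrix(m)
    tot <- rowSums(m)
    filtered <- tot <= minTotal
    isDE <- !filtered & R >= cutoff
    f <- normalizeFrequencies(m)
    libs <- colnames(m)
    assigned <- rep(list(character(0)), nrow(m))
    for (i in which(isDE)) {
        fi <- f[i, ]
        ord <- order(-fi, seq_along(fi))   # ties: first column wins
        ord <- ord[fi[ord] > 0]
        assigned[[i]] <- libs[utils::head(ord, 2L)]
    }
    DataFrame(tu_id = rownames(m), R = unname(R), total = unname(tot),
              filtered_low_count = unname(filtered), is_de = unname(isDE),
              assigned = CharacterList(assigned),
              row.names = rownames(m))
}

#' Constitutively expressed TUs
#'
#' TUs observed at least once in *every* library whose R value is below
#' the cutoff: expressed everywhere, with no evidence of differential
#' representation. In practice a small set (useful e.g. for identifying
#' constitutive promoters).
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @param cutoff positive R cutoff.
#' @return character vector of TU ids.
#' @export
constitutiveSet <- function(x, cutoff) {
    if (cutoff <= 0) stop("cutoff must be positive")
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    R <- .rValuesMatrix(m)
    everywhere <- rowSums(m >= 1) == ncol(m)
    rownames(m)[everywhere & R < cutoff]
}
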