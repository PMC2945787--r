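#' Pairwise profile distances
#'
#' Distance matrix over the rows of `m`. `"uncentered"` is the uncentered
#' Pearson correlation distance 1 - sum(xy) / sqrt(sum(x^2) sum(y^2))
#' (the default of the classic Cluster program); `"pearson"` is 1 minus
#' the centered correlation; `"euclidean"` delegates to [stats::dist()].
#'
#' @param m numeric matrix; items are rows.
#' @param method one of `"uncentered"`, `"pearson"`, `"euclidean"`.
#' @return a `dist` object.
#' @export
profileDist <- function(m, method = c("uncentered", "pearson", "euclidean")) {
    method <- match.arg(method)
    m <- as.matrix(m)
    if (nrow(m) < 2L) stop("need at least 2 items to compute distances")
    if (method == "euclidean") return(stats::dist(m))
    if (method == "uncentered") {
        nrm <- sqrt(rowSums(m^2))
        bad <- which(nrm == 0)
        if (length(bad))
            stop(sprintf("all-zero item '%s' has no uncentered correlation",
                 rownames(m)[bad[1L]]))
        d <- 1 - tcrossprod(m / nrm)
    } else {
        v <- apply(m, 1L, stats::sd)
        bad <- which(v == 0)
        if (length(bad))
            stop(sprintf("constant item '%s' has no centered correlation",
                 rownames(m)[bad[1L]]))
        d <- 1 - stats::cor(t(m))
    }
    d[d < 0] <- 0   # guard tiny negative rounding
    stats::as.dist(d)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of TUs (rows) or libraries (columns) of a
#' frequency matrix, defaulting to uncentered Pearson correlation
#' distance with average linkage — the defaults of the Cluster 2.11 /
#' Java TreeView toolchain. Deterministic for identical inputs.
#'
#' @param f frequency (or count) matrix, or an [ESTCountSet-class]
#'   (frequencies are used).
#' @param axis cluster `"rows"` (TUs) or `"columns"` (libraries).
#' @param distance distance for [profileDist()].
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return an object of class `hclust` with item labels.
#' @export
hierarchicalCluster <- function(f, axis = c("rows", "columns"),
                                distance = "uncentered",
                                linkage = "average") {
    axis <- match.arg(axis)
    m <- if (is(f, "ESTCountSet")) estFrequencies(f) else as.matrix(f)
    if (axis == "columns") m <- t(m)
    stats::hclust(profileDist(m, distance), method = linkage)
}

#' Correspondence analysis of a nonnegative table
#'
#' Standard (chi-square) correspondence analysis: the table is scaled to
#' a correspondence matrix P summing to 1, the standardized residuals
#' \deqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}
#' are decomposed by SVD, and items are placed in principal coordinates
#' (singular vectors scaled by masses and singular values). The k-th axis
#' carries an inertia equal to the squared singular value; the total
#' inertia equals the table's chi-square statistic divided by its grand
#' total. Axes are ordered by decreasing inertia.
#'
#' @param m nonnegative matrix with no all-zero row or column, or an
#'   [ESTCountSet-class] (counts are used).
#' @param nAxes number of axes to retain (default: all with inertia above
#'   `tol`).
#' @param tol relative tolerance for discarding numerically null axes.
#' @return a [CAResult-class]. A rank-0 table (all rows proportional)
#'   yields `totalInertia` 0 and zero axes.
#' @export
correspondenceAnalysis <- function(m, nAxes = NULL, tol = 1e-10) {
    m <- if (is(m, "ESTCountSet")) estCounts(m) else as.matrix(m)
    if (any(m < 0)) stop("table must be nonnegative")
    if (any(rowSums(m) == 0)) stop("all-zero row in table")
    if (any(colSums(m) == 0)) stop("all-zero column in table")
    P <- m / sum(m)
    r <- rowSums(P); cc <- colSums(P)
    S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
    sv <- svd(S)
    keep <- which(sv$d > tol * max(sv$d, 1))
    if (!is.null(nAxes)) keep <- utils::head(keep, nAxes)
    d <- sv$d[keep]
    rowCo <- sweep(sv$u[, keep, drop = FALSE] / sqrt(r), 2L, d, "*")
    colCo <- sweep(sv$v[, keep, drop = FALSE] / sqrt(cc), 2L, d, "*")
    axisNames <- sprintf("F%d", seq_along(keep))
    dimnames(rowCo) <- list(rownames(m), axisNames)
    dimnames(colCo) <- list(colnames(m), axisNames)
    totIn <- sum(sv$d^2)
    new("CAResult",
        rowCoords = rowCo, colCoords = colCo,
        singularValues = d, inertia = d^2,
        inertiaFraction = if (totIn > 0) d^2 / totIn else numeric(0),
        totalInertia = totIn)
}

#' @rdname CAResult-class
#' @export
setMethod("rowCoords", "CAResult", function(x) x@rowCoords)

#' @rdname CAResult-class
#' @export
setMethod("colCoords", "CAResult", function(x) x@colCoords)

#' @rdname CAResult-class
#' @export
setMethod("inertiaFractions", "CAResult", function(x) x@inertiaFraction)

#' @rdname CAResult-class
#' @export
setMethod("totalInertia", "CAResult", function(x) x@totalInertia)

#' @rdname CAResult-class
#' @export
setMethod("show", "CAResult", function(object) {
    k <- length(object@inertia)
    cat(sprintf("CAResult: %d axes, total inertia %.4g\n",
        k, object@totalInertia))
    if (k) {
        fr <- utils::head(object@inertiaFraction, 4L)
        cat("  inertia fractions:",
            paste(sprintf("%s %.1f%%", names(fr) <- NULL,
                  100 * fr), collapse = ", "), "\n")
    }
})

#' Principal component analysis of frequency profiles
#'
#' Plain PCA on the (optionally column-centered) frequency matrix, as an
#' alternative ordination to [correspondenceAnalysis()].
#'
#' @param f frequency matrix or [ESTCountSet-class].
#' @param ... passed to [stats::prcomp()].
#' @return a `prcomp` object.
#' @export
profilePCA <- function(f, ...) {
    m <- if (is(f, "ESTCountSet")) estFrequencies(f) else as.matrix(f)
    stats::prcomp(m, ...)
}

# Node labels for TreeView files: leaves keep their original (input)
# index; internal nodes are numbered in merge order.
.treeviewNodes <- function(hc, leafPrefix) {
    nm <- nrow(hc$merge)
    lab <- function(v) ifelse(v < 0, sprintf("%s%dX", leafPrefix, -v),
                              sprintf("NODE%dX", v))
    data.frame(node = sprintf("NODE%dX", seq_len(nm)),
               left = lab(hc$merge[, 1L]),
               right = lab(hc$merge[, 2L]),
               score = 1 - hc$height,
               stringsAsFactors = FALSE)
}

#' Export clustered frequencies for Java TreeView
#'
#' Writes the CDT/GTR/ATR file triple understood by Java TreeView: the
#' data table reordered by the dendrogram leaf orders plus the row and
#' column merge trees. Scores stored in the tree files are `1 - height`
#' (correlation-like, decreasing towards the root).
#'
#' @param f frequency matrix or [ESTCountSet-class]; values are written
#'   as-is.
#' @param rowDendrogram,colDendrogram `hclust` objects from
#'   [hierarchicalCluster()] over the same rows/columns as `f`; either
#'   may be `NULL` to skip that tree.
#' @param basePath output path without extension; `.cdt`, `.gtr`, `.atr`
#'   are appended.
#' @return named character vector of the files written, invisibly.
#' @export
exportTreeview <- function(f, rowDendrogram = NULL, colDendrogram = NULL,
                           basePath) {
    m <- if (is(f, "ESTCountSet")) estFrequencies(f) else as.matrix(f)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("matrix needs row and column names")
    rord <- seq_len(nrow(m)); cord <- seq_len(ncol(m))
    if (!is.null(rowDendrogram)) {
        if (length(rowDendrogram$order) != nrow(m))
            stop("row dendrogram does not match matrix rows")
        rord <- rowDendrogram$order
    }
    if (!is.null(colDendrogram)) {
        if (length(colDendrogram$order) != ncol(m))
            stop("column dendrogram does not match matrix columns")
        cord <- colDendrogram$order
    }
    files <- c(cdt = paste0(basePath, ".cdt"))
    gid <- sprintf("GENE%dX", rord)
    aid <- sprintf("ARRY%dX", cord)
    con <- file(files["cdt"], "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT",
                       colnames(m)[cord]), collapse = "\t"), con)
    if (!is.null(colDendrogram))
        writeLines(paste(c("AID", "", "", "", aid), collapse = "\t"), con)
    writeLines(paste(c("EWEIGHT", "", "", "",
                       rep("1", length(cord))), collapse = "\t"), con)
    dat <- m[rord, cord, drop = FALSE]
    body <- paste(gid, rownames(m)[rord], rownames(m)[rord], "1",
                  apply(dat, 1L, function(v)
                      paste(format(v, trim = TRUE, digits = 10),
                            collapse = "\t")),
                  sep = "\t")
    writeLines(body, con)
    if (!is.null(rowDendrogram)) {
        files["gtr"] <- paste0(basePath, ".gtr")
        utils::write.table(.treeviewNodes(rowDendrogram, "GENE"),
            files["gtr"], sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(colDendrogram)) {
        files["atr"] <- paste0(basePath, ".atr")
        utils::write.table(.treeviewNodes(colDendrogram, "ARRY"),
            files["atr"], sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    invisible(files)
}
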