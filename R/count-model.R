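#' Construct an ESTCountSet from a count matrix
#'
#' @param counts numeric matrix of nonnegative whole numbers with TU ids
#'   as rownames and library ids as colnames. Row and column order is
#'   preserved; all downstream tie-breaks refer to this order.
#' @param rowData,colData optional annotation passed through to the
#'   underlying [SummarizedExperiment::SummarizedExperiment].
#'
#' @return a validated [ESTCountSet-class].
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, dimnames = list(c("T1", "T2"), c("L1", "L2")))
#' x <- ESTCountSet(m)
#' librarySizes(x)
#' @export
ESTCountSet <- function(counts, rowData = NULL, colData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    args <- list(assays = list(counts = counts))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    new("ESTCountSet", se)
}

#' @rdname ESTCountSet-class
#' @export
setMethod("estCounts", "ESTCountSet", function(x) assay(x, "counts"))

#' @rdname ESTCountSet-class
#' @export
setMethod("librarySizes", "ESTCountSet", function(x) colSums(estCounts(x)))

#' @rdname ESTCountSet-class
#' @export
setMethod("show", "ESTCountSet", function(object) {
    m <- estCounts(object)
    cat(sprintf("ESTCountSet: %d TUs x %d libraries, %s cDNAs\n",
        nrow(m), ncol(m), format(sum(m), big.mark = ",")))
    callNextMethod()
})

#' Read a TU-by-library count table
#'
#' Reads a tab-separated count table whose header row holds library ids
#' and whose first column holds TU ids. Library sizes are recomputed from
#' the column sums; row and column order are preserved from the file.
#'
#' @param path path to a TSV file.
#' @return an [ESTCountSet-class].
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
        colClasses = "character", check.names = FALSE,
        stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count table needs a TU id column and at least one library")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate TU id '%s'", ids[duplicated(ids)][1L]))
    libs <- colnames(df)[-1L]
    if (anyDuplicated(libs))
        stop(sprintf("duplicate library id '%s'", libs[duplicated(libs)][1L]))
    m <- matrix(NA_real_, nrow(df), length(libs),
                dimnames = list(ids, libs))
    for (j in seq_along(libs)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v) | v != round(v))
        if (length(bad))
            stop(sprintf("malformed cell at TU '%s', library '%s': '%s'",
                 ids[bad[1L]], libs[j], df[[j + 1L]][bad[1L]]))
        neg <- which(v < 0)
        if (length(neg))
            stop(sprintf("negative count at TU '%s', library '%s'",
                 ids[neg[1L]], libs[j]))
        m[, j] <- v
    }
    zero <- which(rowSums(m) < 1)
    if (length(zero))
        stop(sprintf("all-zero row for TU '%s'", ids[zero[1L]]))
    ESTCountSet(m)
}

#' Write a count table as TSV
#'
#' Inverse of [readCountTable()]: writes a header of library ids with a
#' leading `tu_id` column.
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    df <- data.frame(tu_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Build a count matrix from per-cDNA assignments
#'
#' Aggregates a cDNA -> TU -> library assignment list (the output of an
#' external clustering/alignment step) into an [ESTCountSet-class]. The
#' total of the count matrix equals the number of assignment records
#' (each cDNA is counted exactly once).
#'
#' @param assignments data.frame with columns `cdna_id`, `tu_id`,
#'   `library_id` (extra columns ignored).
#' @return an [ESTCountSet-class]; TU and library order follow first
#'   appearance in the records.
#' @export
buildCountMatrix <- function(assignments) {
    req <- c("cdna_id", "tu_id", "library_id")
    if (!all(req %in% colnames(assignments)))
        stop("assignments need columns cdna_id, tu_id, library_id")
    if (nrow(assignments) == 0L)
        stop("no assignments")
    dup <- duplicated(assignments$cdna_id)
    if (any(dup))
        stop(sprintf("duplicate cdna_id '%s' (a cDNA counted twice)",
             assignments$cdna_id[dup][1L]))
    tu <- factor(assignments$tu_id, levels = unique(assignments$tu_id))
    lib <- factor(assignments$library_id,
                  levels = unique(assignments$library_id))
    m <- table(tu, lib)
    m <- matrix(as.numeric(m), nrow = nlevels(tu),
                dimnames = list(levels(tu), levels(lib)))
    ESTCountSet(m)
}

#' Normalize counts to within-library frequencies
#'
#' Divides each column of the count matrix by its library size (column
#' sum), so each column sums to 1. Frequencies put libraries of different
#' depths on a common scale and are the input to profile clustering and
#' the R statistic's expected values.
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @return numeric matrix of frequencies with the same dimnames.
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, dimnames = list(c("T1", "T2"), c("L1", "L2")))
#' normalizeFrequencies(ESTCountSet(m))
#' @export
normalizeFrequencies <- function(x) {
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    N <- colSums(m)
    if (any(N <= 0))
        stop(sprintf("zero-size library '%s'", colnames(m)[which(N <= 0)[1L]]))
    sweep(m, 2L, N, "/")
}

#' @rdname normalizeFrequencies
#' @param x an `ESTCountSet`
#' @export
setMethod("estFrequencies", "ESTCountSet", function(x) normalizeFrequencies(x))

#' Per-library redundancy statistics
#'
#' For each library: the number of cDNAs sequenced (column sum), the
#' number of distinct TUs observed, singletons (TUs seen exactly once),
#' multi-copy TUs (seen at least twice), and the redundancy percentage
#' `100 * (1 - n_tus / n_cdnas)` — the fraction of a library's cDNAs that
#' are repeat observations of already-seen TUs.
#'
#' @param x an [ESTCountSet-class] or count matrix.
#' @return a [S4Vectors::DataFrame] with one row per library.
#' @export
setMethod("libraryStats", "ESTCountSet", function(x) {
    m <- estCounts(x)
    nC <- colSums(m)
    nT <- colSums(m >= 1)
    nS <- colSums(m == 1)
    nM <- colSums(m >= 2)
    DataFrame(library_id = colnames(m),
              n_cdnas = as.integer(nC),
              n_tus = as.integer(nT),
              n_singletons = as.integer(nS),
              n_multi = as.integer(nM),
              redundancy_pct = unname(100 * (1 - nT / nC)),
              row.names = colnames(m))
})

#' @rdname libraryStats
#' @export
setMethod("libraryStats", "matrix", function(x) libraryStats(ESTCountSet(x)))

#' Published library summary table
#'
#' The per-library summary of the 16 Phaeodactylum tricornutum cDNA
#' libraries (culture condition codes, cDNAs sequenced, contigs,
#' singletons, TUs and the published redundancy percentage), shipped as a
#' plain-text table for bookkeeping checks and worked examples. Note the
#' published `%R` column is not exactly `100 * (1 - TUs/cDNAs)` (its
#' formula is undocumented); [libraryStats()] uses the explicit formula.
#'
#' @return data.frame with one row per library.
#' @export
libraryTable <- function() {
    path <- system.file("extdata", "pt_library_summary.tsv",
                        package = "estDGE", mustWork = TRUE)
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}
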