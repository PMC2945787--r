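#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet
NULL

# Sense codons (61) under the standard genetic code, their amino acids,
# and synonymous families. Kept as closures so a different code table can
# be injected where needed.
.codonTables <- function(code = Biostrings::GENETIC_CODE) {
    sense <- names(code)[code != "*"]
    fam <- split(sense, code[sense])
    single <- names(fam)[lengths(fam) == 1L]
    list(code = code, sense = sense, families = fam,
         singleCodons = unlist(fam[single], use.names = FALSE))
}
.STD <- NULL  # initialized at load time (needs Biostrings)

.stdTables <- function() {
    if (is.null(.STD)) .codonTables() else .STD
}

#' Codon counts per coding sequence
#'
#' Tallies sense codons for each CDS, applying the inclusion rules of a
#' codon-usage screen: sequences must start with ATG, consist only of
#' A/C/G/T, have length divisible by 3, and contain no internal stop
#' codon. A terminal stop codon is ignored (not counted); stop codons
#' never enter the tallies. Excluded genes are reported with a reason.
#'
#' @param cds a [Biostrings::DNAStringSet] or named character vector of
#'   DNA sequences.
#' @return list with `counts` (integer matrix, genes x 61 sense codons)
#'   and `excluded` (data.frame `gene_id`, `reason`).
#' @examples
#' codonCounts(c(g1 = "ATGTTTTTC"))$counts[, c("ATG", "TTT", "TTC")]
#' @export
codonCounts <- function(cds) {
    if (is(cds, "DNAStringSet")) cds <- as.character(cds)
    if (is.null(names(cds)))
        names(cds) <- paste0("gene", seq_along(cds))
    tb <- .stdTables()
    stops <- names(tb$code)[tb$code == "*"]
    counts <- matrix(0L, 0L, length(tb$sense),
                     dimnames = list(NULL, tb$sense))
    keptIds <- character(0)
    exId <- character(0); exWhy <- character(0)
    rows <- list()
    for (i in seq_along(cds)) {
        s <- toupper(cds[[i]])
        id <- names(cds)[i]
        reason <- NULL
        if (grepl("[^ACGT]", s)) reason <- "ambiguous base"
        else if (nchar(s) %% 3L != 0L) reason <- "length not multiple of 3"
        else if (substr(s, 1L, 3L) != "ATG") reason <- "does not start with ATG"
        if (is.null(reason)) {
            nc <- nchar(s) / 3L
            cod <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
            if (cod[nc] %in% stops) cod <- cod[-nc]
            if (any(cod %in% stops)) reason <- "internal stop codon"
            else if (length(cod) == 0L) reason <- "no sense codons"
        }
        if (!is.null(reason)) {
            exId <- c(exId, id); exWhy <- c(exWhy, reason)
        } else {
            rows[[length(rows) + 1L]] <-
                table(factor(cod, levels = tb$sense))
            keptIds <- c(keptIds, id)
        }
    }
    if (length(rows)) {
        counts <- do.call(rbind, lapply(rows, as.integer))
        dimnames(counts) <- list(keptIds, tb$sense)
    }
    list(counts = counts,
         excluded = data.frame(gene_id = exId, reason = exWhy,
                               stringsAsFactors = FALSE))
}

# RSCU of a single codon-count vector: count / (family total / degeneracy).
# Families with zero total yield NA (missing, not zero).
.rscuVector <- function(cnt, tb = .stdTables()) {
    out <- setNames(rep(NA_real_, length(tb$sense)), tb$sense)
    for (fam in tb$families) {
        tot <- sum(cnt[fam])
        if (tot > 0) out[fam] <- cnt[fam] / (tot / length(fam))
    }
    out
}

#' Relative synonymous codon usage
#'
#' RSCU of codon k in a synonymous family of degeneracy d with family
#' total T is `count_k / (T / d)`: the observed count relative to the
#' equal-usage expectation. Within every observed family the RSCU values
#' sum to d; families unobserved in a gene are reported as `NA` (missing,
#' not zero).
#'
#' @param counts codon-count matrix (genes x 61, as from
#'   [codonCounts()]`$counts`) or a single named count vector.
#' @param pooled if TRUE and `counts` is a matrix, counts are summed over
#'   genes first and a single RSCU vector is returned.
#' @return named numeric vector (pooled or single gene) or matrix of
#'   per-gene RSCU values.
#' @examples
#' rscu(c(TTT = 3, TTC = 1))[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(counts, pooled = FALSE) {
    tb <- .stdTables()
    full <- function(v) {
        out <- setNames(numeric(length(tb$sense)), tb$sense)
        out[names(v)[names(v) %in% tb$sense]] <-
            v[names(v) %in% tb$sense]
        out
    }
    if (is.matrix(counts)) {
        if (pooled) return(.rscuVector(full(colSums(counts)), tb))
        out <- t(apply(counts, 1L, function(v) .rscuVector(full(v), tb)))
        colnames(out) <- tb$sense
        return(out)
    }
    .rscuVector(full(counts), tb)
}

#' Relative adaptiveness weights from a reference gene set
#'
#' Pools the codon counts of a highly expressed reference set (typically
#' genes supported by more than 30 cDNAs, see [referenceGeneSet()]) and
#' derives, within each synonymous family, w = RSCU / max(RSCU). Codons
#' unobserved in an otherwise observed family receive a pseudo-count of
#' 0.5 before RSCU, which avoids zero weights while penalizing rare
#' codons; fully unobserved families fall back to uniform weights of 1.
#' Single-codon families (ATG, TGG) have w = 1 and are excluded from CAI
#' products.
#'
#' @param reference codon-count matrix or pooled named vector for the
#'   reference genes.
#' @param description free-text provenance of the reference set.
#' @return a [CAIWeights-class].
#' @export
caiWeights <- function(reference, description = "pooled reference set") {
    tb <- .stdTables()
    cnt <- if (is.matrix(reference)) colSums(reference) else reference
    if (sum(cnt) <= 0) stop("empty reference set")
    v <- setNames(numeric(length(tb$sense)), tb$sense)
    v[names(cnt)[names(cnt) %in% tb$sense]] <- cnt[names(cnt) %in% tb$sense]
    w <- setNames(rep(1, length(tb$sense)), tb$sense)
    for (fam in tb$families) {
        if (length(fam) == 1L) next
        x <- v[fam]
        if (sum(x) == 0) next           # unobserved family: uniform w = 1
        x[x == 0] <- 0.5
        r <- x / (sum(x) / length(fam))
        w[fam] <- r / max(r)
    }
    new("CAIWeights", weights = w, referenceDescription = description)
}

#' @rdname CAIWeights-class
#' @export
setMethod("codonWeights", "CAIWeights", function(x) x@weights)

#' @rdname CAIWeights-class
#' @export
setMethod("show", "CAIWeights", function(object) {
    cat(sprintf("CAIWeights (%s): %d codons with w = 1\n",
        object@referenceDescription, sum(object@weights >= 1 - 1e-12)))
})

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights over a gene's
#' codons, excluding ATG, TGG (single-codon families) and stops:
#' `exp(sum(n_k log w_k) / sum(n_k))`. CAI is 1 for a gene using only
#' family-preferred codons and is invariant to gene length for fixed
#' codon composition.
#'
#' @param gene codon-count vector (named) or matrix of genes (rows).
#' @param weights a [CAIWeights-class].
#' @return numeric CAI per gene, in (0, 1].
#' @export
cai <- function(gene, weights) {
    tb <- .stdTables()
    w <- codonWeights(weights)
    use <- setdiff(tb$sense, tb$singleCodons)   # the 59 informative codons
    one <- function(v) {
        x <- setNames(numeric(length(tb$sense)), tb$sense)
        x[names(v)[names(v) %in% tb$sense]] <- v[names(v) %in% tb$sense]
        n <- x[use]
        if (sum(n) == 0) stop("no countable codons for CAI")
        exp(sum(n * log(w[use])) / sum(n))
    }
    if (is.matrix(gene)) apply(gene, 1L, one) else one(gene)
}

#' GC content at third codon positions
#'
#' Fraction of a gene's counted sense codons ending in G or C, computed
#' from codon counts.
#'
#' @param counts codon-count vector or matrix (genes x codons).
#' @return numeric GC3 per gene.
#' @export
gc3 <- function(counts) {
    one <- function(v) {
        third <- substr(names(v), 3L, 3L)
        sum(v[third %in% c("G", "C")]) / sum(v)
    }
    if (is.matrix(counts)) apply(counts, 1L, one) else one(counts)
}

#' Select a highly expressed reference gene set
#'
#' Genes whose expression-level index exceeds a threshold. The index is
#' the total (default) or maximum cDNA count across libraries.
#'
#' @param x an [ESTCountSet-class] or count matrix whose rows are genes.
#' @param minCdnas threshold: genes with index strictly greater than this
#'   are selected (default 30).
#' @param stat `"sum"` (default) or `"max"`.
#' @return character vector of gene ids.
#' @export
referenceGeneSet <- function(x, minCdnas = 30, stat = c("sum", "max")) {
    stat <- match.arg(stat)
    m <- if (is(x, "ESTCountSet")) estCounts(x) else as.matrix(x)
    idx <- if (stat == "sum") rowSums(m) else apply(m, 1L, max)
    rownames(m)[idx > minCdnas]
}

#' Correspondence analysis of codon usage
#'
#' Runs the shared CA engine over a genes-by-codons RSCU table restricted
#' to the 59 informative codons (61 sense codons minus the single-codon
#' families ATG and TGG). Families missing in a gene (NA RSCU) are
#' imputed as family-uniform (RSCU = 1), the no-information value. The
#' first axis (F1) typically captures the dominant codon-bias gradient;
#' codon F1 coordinates serve as an estimator of the relative usage of
#' degenerate codons, and gene F1 coordinates rank genes along the bias
#' gradient.
#'
#' @param rscuMatrix per-gene RSCU matrix from `rscu(counts)`; columns
#'   may be 61 (single-codon families dropped internally) or 59 codons.
#' @param nAxes axes to retain (default 4).
#' @return list with `ca` (a [CAResult-class]), `geneF1`, `codonF1`
#'   (named numeric coordinates on the first axis).
#' @export
codonCA <- function(rscuMatrix, nAxes = 4L) {
    tb <- .stdTables()
    keep <- setdiff(intersect(colnames(rscuMatrix), tb$sense),
                    tb$singleCodons)
    if (length(keep) < 2L) stop("need at least 2 informative codons")
    m <- rscuMatrix[, keep, drop = FALSE]
    m[is.na(m)] <- 1
    ca <- correspondenceAnalysis(m, nAxes = nAxes)
    k <- ncol(rowCoords(ca))
    list(ca = ca,
         geneF1 = if (k) rowCoords(ca)[, 1L] else
             setNames(rep(0, nrow(m)), rownames(m)),
         codonF1 = if (k) colCoords(ca)[, 1L] else
             setNames(rep(0, ncol(m)), colnames(m)))
}
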