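.PHYLETIC_CLASSES <- c("core", "diatom_specific", "species_specific",
                       "unclassified")

#' Build a TU annotation table
#'
#' One row per TU: InterPro domain ids (possibly empty), GO term ids,
#' a phyletic class (`core` = conserved across the reference eukaryotic
#' genomes, `diatom_specific`, `species_specific`, or `unclassified`),
#' and an optional single-letter COG category.
#'
#' @param tu_id unique TU identifiers.
#' @param domain_ids,go_terms lists (or [IRanges::CharacterList]s) of ids
#'   per TU; missing entries become empty sets.
#' @param phyletic_class character; unknown/NA values become
#'   `"unclassified"`.
#' @param cog_class optional single letters (NA allowed).
#' @return a [S4Vectors::DataFrame] keyed by `tu_id`.
#' @export
makeAnnotationTable <- function(tu_id, domain_ids = NULL, go_terms = NULL,
                                phyletic_class = NULL, cog_class = NULL) {
    n <- length(tu_id)
    if (anyDuplicated(tu_id)) stop("duplicate tu_id in annotation")
    emptyCL <- function(x) {
        if (is.null(x)) return(CharacterList(rep(list(character(0)), n)))
        x <- as(x, "CharacterList")
        if (length(x) != n) stop("annotation column length mismatch")
        x
    }
    pc <- if (is.null(phyletic_class)) rep("unclassified", n)
          else as.character(phyletic_class)
    pc[is.na(pc) | !pc %in% .PHYLETIC_CLASSES] <- "unclassified"
    cg <- if (is.null(cog_class)) rep(NA_character_, n)
          else as.character(cog_class)
    DataFrame(tu_id = tu_id,
              domain_ids = emptyCL(domain_ids),
              go_terms = emptyCL(go_terms),
              phyletic_class = pc,
              cog_class = cg,
              row.names = tu_id)
}

#' Read an annotation table from TSV
#'
#' Expects columns `tu_id`, `domain_ids`, `go_terms` (semicolon-joined;
#' empty for none), `phyletic_class`, `cog_class`.
#'
#' @param path TSV path.
#' @return a [S4Vectors::DataFrame] as from [makeAnnotationTable()].
#' @export
readAnnotationTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
        colClasses = "character", stringsAsFactors = FALSE)
    splitIds <- function(v)
        lapply(v, function(s) if (is.na(s) || s == "") character(0)
               else strsplit(s, ";", fixed = TRUE)[[1L]])
    makeAnnotationTable(df$tu_id,
        domain_ids = splitIds(df$domain_ids),
        go_terms = splitIds(df$go_terms),
        phyletic_class = df$phyletic_class,
        cog_class = ifelse(df$cog_class == "", NA, df$cog_class))
}

#' Classify TUs as PDF or POF
#'
#' Proteins with defined functions (PDF) carry at least one InterPro
#' domain; proteins with obscure functions (POF) carry none. Every TU is
#' exactly one of the two.
#'
#' @param annotation table from [makeAnnotationTable()].
#' @return named character vector (`"PDF"`/`"POF"`) over all TUs.
#' @export
classifyPofPdf <- function(annotation) {
    n <- lengths(annotation$domain_ids)
    out <- ifelse(n > 0, "PDF", "POF")
    names(out) <- annotation$tu_id
    out
}

#' GO-term over-representation in a DE set
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of each GO
#' term's membership in the differentially expressed set against the
#' background of expressed TUs. Terms never seen in the DE set are
#' reported but can never be significant. No multiple-testing correction
#' is applied by default (the raw screen at `alpha`); Benjamini-Hochberg
#' adjustment is available via `adjust = "BH"`.
#'
#' @param deSet TU ids called differentially expressed; must be a subset
#'   of `background`.
#' @param background TU ids of all expressed TUs considered.
#' @param annotation table from [makeAnnotationTable()] covering the
#'   background.
#' @param alpha significance level on the (possibly adjusted) p-value;
#'   default 0.001.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param term_column annotation column holding the term sets (default
#'   `"go_terms"`; use `"domain_ids"` for InterPro over-representation).
#' @return a [S4Vectors::DataFrame], one row per term seen in the
#'   background: `term_id`, `k_de`, `n_de`, `k_bg`, `n_bg`, `p_value`,
#'   `significant`; sorted by p-value.
#' @export
goEnrichment <- function(deSet, background, annotation, alpha = 0.001,
                         adjust = c("none", "BH"),
                         term_column = "go_terms") {
    adjust <- match.arg(adjust)
    if (length(background) == 0L) stop("empty background")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (!all(deSet %in% background))
        stop("deSet must be a subset of background")
    terms <- annotation[[term_column]]
    names(terms) <- annotation$tu_id
    bgTerms <- terms[intersect(background, names(terms))]
    deTerms <- terms[intersect(deSet, names(terms))]
    nBg <- length(background)
    nDe <- length(deSet)
    kBg <- table(unlist(bgTerms, use.names = FALSE))
    if (length(kBg) == 0L)
        return(DataFrame(term_id = character(0), k_de = integer(0),
                         n_de = integer(0), k_bg = integer(0),
                         n_bg = integer(0), p_value = numeric(0),
                         significant = logical(0)))
    kDeTab <- table(unlist(deTerms, use.names = FALSE))
    kDe <- ifelse(names(kBg) %in% names(kDeTab),
                  as.integer(kDeTab[names(kBg)]), 0L)
    kBgv <- as.integer(kBg)
    # upper tail: P(X >= k_de) for X ~ Hypergeom(k_bg, n_bg - k_bg, n_de)
    p <- stats::phyper(kDe - 1L, kBgv, nBg - kBgv, nDe, lower.tail = FALSE)
    padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
    out <- DataFrame(term_id = names(kBg),
                     k_de = kDe, n_de = nDe, k_bg = kBgv, n_bg = nBg,
                     p_value = p,
                     significant = kDe > 0 & padj < alpha)
    if (adjust == "BH") out$p_adjusted <- padj
    out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Mean frequency profile per annotation class
#'
#' For each library and each level of an annotation class (by default the
#' phyletic class) the mean frequency of its member TUs: the per-class
#' expression overlay used to compare e.g. core vs species-specific
#' genes across conditions.
#'
#' @param x an [ESTCountSet-class].
#' @param annotation table from [makeAnnotationTable()]; TUs of `x`
#'   absent from the table are treated as `"unclassified"`.
#' @param class_column annotation column with class labels.
#' @return matrix (classes x libraries) of mean frequencies.
#' @export
classProfile <- function(x, annotation, class_column = "phyletic_class") {
    f <- estFrequencies(x)
    cls <- setNames(rep("unclassified", nrow(f)), rownames(f))
    hit <- intersect(rownames(f), annotation$tu_id)
    cls[hit] <- as.character(annotation[hit, class_column])
    cls[is.na(cls)] <- "unclassified"
    rowsByClass <- split(seq_len(nrow(f)), cls)
    out <- t(vapply(rowsByClass, function(idx)
        colMeans(f[idx, , drop = FALSE]), numeric(ncol(f))))
    colnames(out) <- colnames(f)
    out
}

#' Per-COG-category expression summary
#'
#' Counts of TUs and their mean frequency per single-letter COG category
#' (TUs without a category are dropped).
#'
#' @param x an [ESTCountSet-class].
#' @param annotation table from [makeAnnotationTable()].
#' @return a [S4Vectors::DataFrame] with `cog_class`, `n_tus`,
#'   `mean_frequency`.
#' @export
cogSummary <- function(x, annotation) {
    f <- estFrequencies(x)
    cog <- setNames(annotation$cog_class, annotation$tu_id)[rownames(f)]
    keep <- !is.na(cog)
    if (!any(keep))
        return(DataFrame(cog_class = character(0), n_tus = integer(0),
                         mean_frequency = numeric(0)))
    idx <- split(which(keep), cog[keep])
    DataFrame(cog_class = names(idx),
              n_tus = lengths(idx),
              mean_frequency = vapply(idx, function(i)
                  mean(f[i, , drop = FALSE]), numeric(1)))
}

#' Overlap of a DE set with another species through ortholog pairs
#'
#' Given TUs called differentially expressed in species A, a set of genes
#' of interest in species B (e.g. B's DE set under the same treatment),
#' and an ortholog pair table, counts how many DE TUs have at least one
#' ortholog and how many of those hit the B set. A gene may have several
#' ortholog partners.
#'
#' @param deA character; DE TU ids of species A.
#' @param setB character; gene ids of species B.
#' @param pairs data.frame with columns `a_id`, `b_id`.
#' @return list with `n_de_a`, `n_with_ortholog`, `n_overlap`, and
#'   `overlap_pairs` (the pair rows connecting `deA` to `setB`).
#' @export
orthologOverlap <- function(deA, setB, pairs) {
    if (!all(c("a_id", "b_id") %in% colnames(pairs)))
        stop("pairs needs columns a_id, b_id")
    rel <- pairs[pairs$a_id %in% deA, , drop = FALSE]
    hit <- rel[rel$b_id %in% setB, , drop = FALSE]
    list(n_de_a = length(unique(deA)),
         n_with_ortholog = length(unique(rel$a_id)),
         n_overlap = length(unique(hit$a_id)),
         overlap_pairs = hit)
}
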