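#' Simulate a multi-library EST dataset with known ground truth
#'
#' Generates a TU-by-library count matrix emulating a set of
#' non-normalized cDNA libraries, together with an annotation table and a
#' truth table for validating the analysis chain. Per-TU base abundances
#' are log-normal (skewed, so a few TUs dominate, as in real EST
#' catalogues); a designated fraction of TUs receive a condition-specific
#' fold change in their target libraries; each library's counts are drawn
#' multinomially conditioned on its exact size, so column sums match the
#' configured library sizes. TUs never observed are dropped from the
#' output (with a truth-table note), matching the construction invariant
#' that every catalogued TU was seen at least once.
#'
#' Defaults emulate the study design the package targets: 16 libraries
#' whose sizes span 3,541-12,566 cDNAs, heavy-tailed abundances
#' (log-normal sigma 1.5), 5% of TUs differentially expressed at 8-fold
#' in one library each, and a small constitutive set planted at high
#' abundance with a flat profile.
#'
#' @param nTUs number of TUs in the pool.
#' @param nLibraries number of libraries (default 16).
#' @param librarySizes optional integer vector; default: drawn uniformly
#'   in `sizeRange`.
#' @param sizeRange range for random library sizes (default
#'   `c(3541, 12566)`).
#' @param abundanceSigma log-normal sigma of base abundances (default 1.5).
#' @param deFraction fraction of TUs spiked (default 0.05).
#' @param deFoldChange rate multiplier in target libraries (default 8).
#' @param deLibrariesPerTU target libraries per spiked TU (default 1).
#' @param constitutiveFraction fraction of TUs planted as constitutive:
#'   flat profile at the 99th abundance percentile so they are observed
#'   in every library (default 0.001).
#' @param classProportions phyletic-class sampling proportions.
#' @param classAbundance per-class abundance multipliers; core genes are
#'   generally expressed higher than species-specific ones.
#' @param nGoTerms,goRate GO vocabulary size and per-term baseline
#'   annotation probability.
#' @param nLoadedTerms,goLoadFactor number of terms enriched on DE TUs
#'   and the factor by which their probability is multiplied there.
#' @param pdfFraction fraction of TUs given at least one InterPro domain
#'   (default 0.56, the genome-wide PDF share).
#' @param seed optional integer seed; identical seeds reproduce the
#'   dataset bit-identically.
#' @return list with `counts` (an [ESTCountSet-class]), `annotation`
#'   (from [makeAnnotationTable()]) and `truth` (data.frame per TU:
#'   `tu_id`, `is_de`, `target_libraries` (semicolon-joined),
#'   `fold_change`, `is_constitutive`, `phyletic_class`, `has_loaded_term`,
#'   `dropped`).
#' @export
simulateLibraries <- function(nTUs = 5000L, nLibraries = 16L,
        librarySizes = NULL, sizeRange = c(3541L, 12566L),
        abundanceSigma = 1.5,
        deFraction = 0.05, deFoldChange = 8, deLibrariesPerTU = 1L,
        constitutiveFraction = 0.001,
        classProportions = c(core = 0.40, diatom_specific = 0.25,
                             species_specific = 0.25, unclassified = 0.10),
        classAbundance = c(core = 3, diatom_specific = 1.5,
                           species_specific = 1, unclassified = 1),
        nGoTerms = 50L, goRate = 0.03,
        nLoadedTerms = 5L, goLoadFactor = 5,
        pdfFraction = 0.56, seed = NULL) {
    if (deFraction < 0 || constitutiveFraction < 0 ||
        deFraction + constitutiveFraction > 1)
        stop("deFraction + constitutiveFraction must lie in [0, 1]")
    if (deFoldChange < 1) stop("deFoldChange must be >= 1")
    if (nTUs < 2L || nLibraries < 2L) stop("need >= 2 TUs and libraries")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(librarySizes))
        librarySizes <- sample(sizeRange[1L]:sizeRange[2L], nLibraries,
                               replace = TRUE)
    if (any(librarySizes <= 0)) stop("library sizes must be positive")
    nLibraries <- length(librarySizes)
    libs <- sprintf("L%02d", seq_len(nLibraries))
    tus <- sprintf("TU%05d", seq_len(nTUs))

    cls <- sample(names(classProportions), nTUs, replace = TRUE,
                  prob = classProportions)
    a <- stats::rlnorm(nTUs, 0, abundanceSigma) *
         unname(classAbundance[cls])

    nDe <- round(deFraction * nTUs)
    nConst <- round(constitutiveFraction * nTUs)
    roles <- sample(nTUs, nDe + nConst)
    deIdx <- roles[seq_len(nDe)]
    constIdx <- roles[nDe + seq_len(nConst)]
    # constitutive TUs: flat and abundant enough to be seen everywhere
    if (nConst) a[constIdx] <- stats::quantile(a, 0.99)

    targets <- rep(list(character(0)), nTUs)
    for (i in deIdx)
        targets[[i]] <- sort(sample(libs, deLibrariesPerTU))

    rate <- matrix(a, nTUs, nLibraries, dimnames = list(tus, libs))
    for (i in deIdx)
        rate[i, targets[[i]]] <- rate[i, targets[[i]]] * deFoldChange

    counts <- vapply(seq_len(nLibraries), function(j)
        stats::rmultinom(1L, librarySizes[j],
                         rate[, j] / sum(rate[, j]))[, 1L],
        numeric(nTUs))
    dimnames(counts) <- list(tus, libs)
    dropped <- rowSums(counts) == 0

    # annotation: domains for PDFs, GO terms with enrichment on DE TUs
    goIds <- sprintf("GO:%07d", seq_len(nGoTerms))
    loaded <- goIds[seq_len(min(nLoadedTerms, nGoTerms))]
    pRate <- matrix(goRate, nTUs, nGoTerms)
    pRate[deIdx, match(loaded, goIds)] <-
        pmin(1, goRate * goLoadFactor)
    hasTerm <- matrix(stats::runif(nTUs * nGoTerms) < pRate, nTUs)
    goSets <- apply(hasTerm, 1L, function(v) goIds[v], simplify = FALSE)
    isPdf <- stats::runif(nTUs) < pdfFraction
    domSets <- lapply(seq_len(nTUs), function(i)
        if (isPdf[i]) sprintf("IPR%06d", sample(9999L, 1L)) else character(0))
    cogs <- ifelse(stats::runif(nTUs) < 0.3,
                   sample(LETTERS[1:19], nTUs, replace = TRUE),
                   NA_character_)

    truth <- data.frame(
        tu_id = tus,
        is_de = seq_len(nTUs) %in% deIdx,
        target_libraries = vapply(targets, paste, "", collapse = ";"),
        fold_change = ifelse(seq_len(nTUs) %in% deIdx, deFoldChange, 1),
        is_constitutive = seq_len(nTUs) %in% constIdx,
        phyletic_class = cls,
        has_loaded_term =
            rowSums(hasTerm[, match(loaded, goIds), drop = FALSE]) > 0,
        dropped = dropped,
        stringsAsFactors = FALSE)

    keep <- !dropped
    list(counts = ESTCountSet(counts[keep, , drop = FALSE]),
         annotation = makeAnnotationTable(tus[keep],
             domain_ids = domSets[keep], go_terms = goSets[keep],
             phyletic_class = cls[keep], cog_class = cogs[keep]),
         truth = truth,
         loadedTerms = loaded,
         librarySizes = setNames(librarySizes, libs))
}

#' Simulate ortholog pairs between two species
#'
#' Builds an ortholog pair table linking species-A TUs to species-B gene
#' ids, plus species B's own "responder" gene set, with a configurable
#' fraction of conserved responders: the fraction of A's DE TUs whose
#' ortholog is also in B's set.
#'
#' @param tuIds all species-A TU ids.
#' @param deIds the subset of `tuIds` differentially expressed in A.
#' @param orthologRate probability an A TU has an ortholog (default 0.5,
#'   roughly the cross-species mapping rate of diatom DE transcripts).
#' @param conservedFraction probability the ortholog of a DE TU responds
#'   in B too (default 0.4).
#' @param backgroundRate probability a non-DE TU's ortholog is in B's
#'   set anyway (default 0.05).
#' @param seed optional integer seed.
#' @return list with `pairs` (data.frame `a_id`, `b_id`), `setB`
#'   (character) and `truth` (data.frame `a_id`, `has_ortholog`,
#'   `conserved`).
#' @export
simulateOrthologPairs <- function(tuIds, deIds, orthologRate = 0.5,
                                  conservedFraction = 0.4,
                                  backgroundRate = 0.05, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    hasOrt <- stats::runif(length(tuIds)) < orthologRate
    bId <- ifelse(hasOrt, sprintf("B_%s", tuIds), NA_character_)
    isDe <- tuIds %in% deIds
    inB <- hasOrt & stats::runif(length(tuIds)) <
        ifelse(isDe, conservedFraction, backgroundRate)
    list(pairs = data.frame(a_id = tuIds[hasOrt], b_id = bId[hasOrt],
                            stringsAsFactors = FALSE),
         setB = bId[inB],
         truth = data.frame(a_id = tuIds, has_ortholog = hasOrt,
                            conserved = inB, stringsAsFactors = FALSE))
}

#' Simulate coding sequences with tunable codon bias
#'
#' Generates CDSs whose codon usage interpolates between family-uniform
#' (bias 0) and fully preferred (bias 1). At each position an amino acid
#' is drawn uniformly; with probability equal to the gene's bias weight
#' the family-preferred codon is used (C-ending where the family has one,
#' otherwise G-ending), else a codon is drawn uniformly from the family.
#' Genes start with ATG, end with a stop codon, and contain no internal
#' stops by construction.
#'
#' @param nGenes number of genes.
#' @param lengthCodons codons per gene including the start (>= 10).
#' @param biasWeights per-gene bias in `[0, 1]`; default an even gradient
#'   from 0 to 1 across genes.
#' @param seed optional integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame `gene_id`, `bias`).
#' @export
simulateCDS <- function(nGenes, lengthCodons = 300L, biasWeights = NULL,
                        seed = NULL) {
    if (lengthCodons < 10L) stop("lengthCodons must be >= 10")
    if (is.null(biasWeights))
        biasWeights <- if (nGenes == 1L) 0.5
                       else seq(0, 1, length.out = nGenes)
    if (length(biasWeights) != nGenes || any(biasWeights < 0) ||
        any(biasWeights > 1))
        stop("biasWeights must be per-gene values in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    tb <- .stdTables()
    fams <- tb$families
    preferred <- vapply(fams, function(f) {
        cEnd <- f[substr(f, 3L, 3L) == "C"]
        if (length(cEnd)) cEnd[1L]
        else {
            gEnd <- f[substr(f, 3L, 3L) == "G"]
            if (length(gEnd)) gEnd[1L] else f[1L]
        }
    }, character(1))
    aas <- names(fams)
    ids <- sprintf("G%05d", seq_len(nGenes))
    seqs <- vapply(seq_len(nGenes), function(g) {
        b <- biasWeights[g]
        aa <- sample(aas, lengthCodons - 1L, replace = TRUE)
        usePref <- stats::runif(lengthCodons - 1L) < b
        cod <- vapply(seq_along(aa), function(k) {
            f <- fams[[aa[k]]]
            if (usePref[k]) preferred[[aa[k]]]
            else f[sample.int(length(f), 1L)]
        }, character(1))
        paste0("ATG", paste(cod, collapse = ""), "TAA")
    }, character(1))
    list(sequences = DNAStringSet(setNames(seqs, ids)),
         truth = data.frame(gene_id = ids, bias = biasWeights,
                            stringsAsFactors = FALSE))
}
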