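#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' ESTCountSet: TU-by-library EST count matrix
#'
#' An `ESTCountSet` holds nonnegative integer counts of cDNAs (ESTs) per
#' transcriptional unit (TU, rows) and cDNA library (columns). It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"counts"`
#' assay, so row and column annotations travel with the counts. Library
#' sizes are *always* the column sums of the count matrix; they are
#' recomputed on demand and never trusted from a file.
#'
#' Validity requires: a `"counts"` assay of nonnegative whole numbers;
#' unique, non-missing TU and library identifiers; and no all-zero rows
#' (a TU must be observed at least once to be in the catalogue).
#'
#' @seealso [ESTCountSet()] (constructor), [readCountTable()],
#'   [buildCountMatrix()], [normalizeFrequencies()], [libraryStats()]
#' @export
setClass("ESTCountSet", contains = "SummarizedExperiment")

setValidity("ESTCountSet", function(object) {
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    if (!is.numeric(m))
        return("counts must be numeric")
    if (anyNA(m))
        return("counts contain NA")
    if (any(m < 0))
        return("negative count")
    if (any(abs(m - round(m)) > 1e-8))
        return("counts must be whole numbers")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("TU and library identifiers are required as dimnames")
    if (anyDuplicated(rownames(m)))
        return("duplicate TU identifier")
    if (anyDuplicated(colnames(m)))
        return("duplicate library identifier")
    zero <- rowSums(m) < 1
    if (any(zero))
        return(sprintf("all-zero row for TU '%s'", rownames(m)[which(zero)[1L]]))
    TRUE
})

#' Null calibration of the R-value cutoff
#'
#' Result of [calibrateCutoff()]: the empirical null distribution of the
#' log-likelihood R statistic under Poisson resampling of every TU, the
#' cutoff at the requested quantile, and the largest null R observed.
#'
#' @slot cutoff numeric(1); the empirical `quantileTarget` quantile of the
#'   pooled null R values (natural-log units).
#' @slot maxNullR numeric(1); largest R seen in any null replicate.
#' @slot nullR numeric; the pooled null R values (possibly empty if the
#'   calibration was run with `keepNull = FALSE`).
#' @slot nReplicates integer(1); number of whole-matrix replicates drawn.
#' @slot quantileTarget numeric(1) in (0, 1).
#' @slot seed integer(1) or NA; the RNG seed used.
#' @export
setClass("NullCalibration",
    representation(cutoff = "numeric", maxNullR = "numeric",
                   nullR = "numeric", nReplicates = "integer",
                   quantileTarget = "numeric", seed = "integer"))

setValidity("NullCalibration", function(object) {
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
        return("cutoff must be a finite scalar")
    if (object@quantileTarget <= 0 || object@quantileTarget >= 1)
        return("quantileTarget must lie in (0, 1)")
    if (object@maxNullR < object@cutoff)
        return("maxNullR cannot be below the cutoff")
    TRUE
})

#' Correspondence analysis result
#'
#' Result of [correspondenceAnalysis()]: principal coordinates of rows
#' and columns, singular values, per-axis inertia and inertia fractions,
#' and the table's total inertia (the chi-square statistic divided by the
#' grand total).
#'
#' @slot rowCoords,colCoords numeric matrices (items x axes) of principal
#'   coordinates.
#' @slot singularValues numeric; singular values of the standardized
#'   residual matrix, decreasing.
#' @slot inertia numeric; squared singular values.
#' @slot inertiaFraction numeric; `inertia / totalInertia` (sums to 1 over
#'   the full decomposition; empty when totalInertia is 0).
#' @slot totalInertia numeric(1).
#' @export
setClass("CAResult",
    representation(rowCoords = "matrix", colCoords = "matrix",
                   singularValues = "numeric", inertia = "numeric",
                   inertiaFraction = "numeric", totalInertia = "numeric"))

setValidity("CAResult", function(object) {
    if (length(object@totalInertia) != 1L || object@totalInertia < 0)
        return("totalInertia must be a nonnegative scalar")
    if (is.unsorted(rev(object@inertia), strictly = FALSE) &&
        length(object@inertia) > 1L)
        return("inertia must be non-increasing")
    TRUE
})

#' Codon adaptiveness weights for CAI
#'
#' Relative adaptiveness w of each sense codon, derived from the pooled
#' codon usage of a highly expressed reference gene set: within each
#' synonymous family, w = RSCU / max(RSCU), so the family's preferred
#' codon has w = 1. Single-codon families (ATG, TGG) carry w = 1 and are
#' excluded from CAI products.
#'
#' @slot weights named numeric over the 61 sense codons, each in (0, 1].
#' @slot referenceDescription character(1); provenance of the reference
#'   set (free text).
#' @export
setClass("CAIWeights",
    representation(weights = "numeric", referenceDescription = "character"))

setValidity("CAIWeights", function(object) {
    w <- object@weights
    if (length(w) != 61L || is.null(names(w)))
        return("weights must be named over the 61 sense codons")
    if (any(w <= 0) || any(w > 1 + 1e-12))
        return("weights must lie in (0, 1]")
    TRUE
})
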