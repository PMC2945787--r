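#' @rdname ESTCountSet-class
#' @param x,object an `ESTCountSet`
#' @export
setGeneric("estCounts", function(x) standardGeneric("estCounts"))

#' @rdname ESTCountSet-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname normalizeFrequencies
#' @export
setGeneric("estFrequencies", function(x) standardGeneric("estFrequencies"))

#' @rdname libraryStats
#' @export
setGeneric("libraryStats", function(x) standardGeneric("libraryStats"))

#' @rdname NullCalibration-class
#' @param x a `NullCalibration`
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname NullCalibration-class
#' @export
setGeneric("maxNullR", function(x) standardGeneric("maxNullR"))

#' @rdname NullCalibration-class
#' @export
setGeneric("nullRValues", function(x) standardGeneric("nullRValues"))

#' @rdname CAResult-class
#' @param x a `CAResult`
#' @export
setGeneric("rowCoords", function(x) standardGeneric("rowCoords"))

#' @rdname CAResult-class
#' @export
setGeneric("colCoords", function(x) standardGeneric("colCoords"))

#' @rdname CAResult-class
#' @export
setGeneric("inertiaFractions", function(x) standardGeneric("inertiaFractions"))

#' @rdname CAResult-class
#' @export
setGeneric("totalInertia", function(x) standardGeneric("totalInertia"))

#' @rdname CAIWeights-class
#' @param x a `CAIWeights`
#' @export
setGeneric("codonWeights", function(x) standardGeneric("codonWeights"))
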