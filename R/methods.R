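#' @rdname CellSample-class
#' @aliases sampleId,CellSample-method
setMethod("sampleId", "CellSample", function(object) object@sampleId)

#' @rdname CellSample-class
setMethod("groupLabel", "CellSample", function(object) object@groupLabel)

#' @rdname CellSample-class
setReplaceMethod("groupLabel", "CellSample", function(object, value) {
    object@groupLabel <- as.character(value)
    validObject(object)
    object
})

#' @rdname CellSample-class
setMethod("markerNames", "CellSample", function(object) {
    colnames(object@intensities)
})

#' @rdname CellSample-class
setMethod("intensities", "CellSample", function(object) object@intensities)

#' @rdname CellSample-class
setMethod("nCells", "CellSample", function(object) nrow(object@intensities))

setMethod("show", "CellSample", function(object) {
    cat("CellSample '", object@sampleId, "'", sep = "")
    if (nzchar(object@groupLabel)) {
        cat(" [group: ", object@groupLabel, "]", sep = "")
    }
    cat("\n ", nrow(object@intensities), " cells x ",
        ncol(object@intensities), " markers\n", sep = "")
    mk <- colnames(object@intensities)
    cat(" markers:", paste(head(mk, 8), collapse = ", "))
    if (length(mk) > 8) cat(", ...")
    cat("\n")
    invisible(NULL)
})

#' @rdname BoxVector-class
setMethod("sampleId", "BoxVector", function(object) object@sampleId)

#' @rdname BoxVector-class
#' @aliases markerPair
#' @param object a \code{BoxVector}.
#' @export markerPair
setGeneric("markerPair", function(object) standardGeneric("markerPair"))

#' @rdname BoxVector-class
setMethod("markerPair", "BoxVector", function(object) object@pair)

#' @rdname BoxVector-class
setMethod("nBins", "BoxVector", function(object) object@nBins)

#' @rdname BoxVector-class
setMethod("percentages", "BoxVector", function(object) object@percentages)

setMethod("show", "BoxVector", function(object) {
    cat("BoxVector: sample '", object@sampleId, "', pair ",
        object@pair[1], " (x) vs ", object@pair[2], " (y), b = ",
        object@nBins, "\n", sep = "")
    print(round(object@percentages, 3))
    invisible(NULL)
})

#' @rdname CalibrationResult-class
setMethod("calibrationEntries", "CalibrationResult", function(object) {
    object@entries
})

#' @rdname CalibrationResult-class
setMethod("recommendedBins", "CalibrationResult", function(object) {
    object@recommendedB
})

setMethod("show", "CalibrationResult", function(object) {
    cat("CalibrationResult (", object@nSamples, " samples, FPR threshold ",
        object@threshold, ")\n", sep = "")
    print(object@entries, row.names = FALSE)
    cat("recommended number of bins:", object@recommendedB, "\n")
    invisible(NULL)
})

#' @importFrom utils head
NULL
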