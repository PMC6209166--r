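#' @describeIn CellSample-class sample identifier.
#' @param object a \code{CellSample}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @describeIn CellSample-class group label (\code{""} when unlabeled).
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @describeIn CellSample-class replace the group label.
#' @param value replacement value.
#' @export
setGeneric("groupLabel<-", function(object, value) {
    standardGeneric("groupLabel<-")
})

#' @describeIn CellSample-class marker names (column names).
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))

#' @describeIn CellSample-class the cells-x-markers intensity matrix.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @describeIn CellSample-class number of cells (rows).
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @describeIn BoxVector-class number of bins b.
#' @param object a \code{BoxVector} or \code{CalibrationResult}.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @describeIn BoxVector-class the straightened percentage vector,
#'   named by box label.
#' @export
setGeneric("percentages", function(object) standardGeneric("percentages"))

#' @describeIn CalibrationResult-class per-b FPR table.
#' @export
setGeneric("calibrationEntries", function(object) {
    standardGeneric("calibrationEntries")
})

#' @describeIn CalibrationResult-class the recommended (largest safe)
#'   bin number.
#' @export
setGeneric("recommendedBins", function(object) {
    standardGeneric("recommendedBins")
})
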