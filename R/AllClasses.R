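#' @import methods
NULL

#' CellSample: one sample's cell-by-marker intensity matrix
#'
#' The elementary data container of the package, modeled on the per-sample
#' event matrix of list-mode cytometry files: rows are cells (events),
#' columns are markers, values are intensities on whatever scale the user
#' has chosen (typically logicle-transformed).  A sample carries its
#' identifier and an optional group label naming which of a cohort's two
#' groups it belongs to.
#'
#' @slot sampleId character(1), unique sample identifier.
#' @slot groupLabel character(1), group name, or \code{""} when unlabeled.
#' @slot intensities numeric matrix, cells x markers, finite values; column
#'   names are the marker names and must be unique.
#'
#' @seealso [cellSample()] for the user-facing constructor,
#'   [boxPercentages()] for the binning entry point.
#' @export
setClass("CellSample",
    representation(
        sampleId = "character",
        groupLabel = "character",
        intensities = "matrix"
    )
)

setValidity("CellSample", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || is.na(object@sampleId)) {
        msg <- c(msg, "sampleId must be a single non-NA string")
    }
    if (length(object@groupLabel) != 1L || is.na(object@groupLabel)) {
        msg <- c(msg, "groupLabel must be a single non-NA string")
    }
    x <- object@intensities
    if (!is.numeric(x)) {
        msg <- c(msg, "intensities must be a numeric matrix")
    } else {
        if (nrow(x) < 1L) {
            msg <- c(msg, "a CellSample must contain at least one cell")
        }
        mk <- colnames(x)
        if (is.null(mk) || anyNA(mk) || any(mk == "")) {
            msg <- c(msg, "intensities must have non-empty marker column names")
        } else if (anyDuplicated(mk)) {
            msg <- c(msg, sprintf(
                "marker names must be unique (duplicated: %s)",
                paste(unique(mk[duplicated(mk)]), collapse = ", ")
            ))
        }
        if (!all(is.finite(x))) {
            msg <- c(msg, "all intensity values must be finite")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a CellSample
#'
#' @param intensities numeric matrix (cells x markers) or an object
#'   coercible to one; column names become the marker names unless
#'   \code{markerNames} is given.
#' @param sampleId character(1) sample identifier.
#' @param groupLabel character(1) group name; \code{""} for unlabeled.
#' @param markerNames optional character vector overriding the column names.
#'
#' @return A [CellSample-class] object.
#' @examples
#' cs <- cellSample(matrix(rnorm(20), 10, 2,
#'     dimnames = list(NULL, c("CD8", "CCR7"))), sampleId = "s1")
#' markerNames(cs)
#' @export
cellSample <- function(intensities, sampleId = "sample",
                       groupLabel = "", markerNames = NULL) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    if (!is.null(markerNames)) {
        if (length(markerNames) != ncol(intensities)) {
            stop("markerNames length (", length(markerNames),
                 ") does not match the number of columns (",
                 ncol(intensities), ")")
        }
        colnames(intensities) <- markerNames
    }
    new("CellSample",
        sampleId = as.character(sampleId),
        groupLabel = as.character(groupLabel),
        intensities = intensities)
}

#' LogicleParams: parameters of the biexponential logicle scale
#'
#' The logicle display/analysis scale for cytometry intensities is fixed by
#' four numbers: the width of the quasi-linear region around zero \code{w}
#' (decades), the top of the data scale \code{t}, the total number of
#' displayed decades \code{m}, and the additional negative decades \code{a}.
#'
#' @slot w numeric(1), linearization width in decades, \code{0 <= w <= m/2}.
#' @slot t numeric(1), top of scale, \code{> 0}.
#' @slot m numeric(1), total decades, \code{> 0}.
#' @slot a numeric(1), additional negative decades, \code{>= 0}.
#' @export
setClass("LogicleParams",
    representation(w = "numeric", t = "numeric", m = "numeric", a = "numeric")
)

setValidity("LogicleParams", function(object) {
    msg <- NULL
    for (s in c("w", "t", "m", "a")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v)) {
            msg <- c(msg, sprintf("%s must be a single finite number", s))
        }
    }
    if (is.null(msg)) {
        if (object@t <= 0) msg <- c(msg, "t must be > 0")
        if (object@m <= 0) msg <- c(msg, "m must be > 0")
        if (object@w < 0) msg <- c(msg, "w must be >= 0")
        if (object@a < 0) msg <- c(msg, "a must be >= 0")
        if (object@w > object@m) msg <- c(msg, "w must not exceed m")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname LogicleParams-class
#' @param w,t,m,a see the class slots.
#' @return \code{logicleParams()} returns a \code{LogicleParams} object.
#' @examples
#' logicleParams(w = 0.5, t = 262144, m = 4.5)
#' @export
logicleParams <- function(w = 0.5, t = 262144, m = 4.5, a = 0) {
    new("LogicleParams", w = as.numeric(w), t = as.numeric(t),
        m = as.numeric(m), a = as.numeric(a))
}

#' BoxVector: straightened box percentages of one marker pair
#'
#' For one sample and one ordered marker pair, the percentages of cells in
#' the b^2 boxes formed by overlaying two independent b-level equal-frequency
#' binnings.  The percentage in box (i, j) estimates the joint probability
#' that a cell falls in bin i of the x-marker and bin j of the y-marker.
#' Percentages are stored row-major with the x-marker bin as the outer index:
#' B11, B12, ..., B1b, B21, ..., Bbb.
#'
#' @slot sampleId character(1).
#' @slot pair character(2): x-marker then y-marker name.
#' @slot nBins integer(1), the bin number b >= 1.
#' @slot percentages numeric(b^2) in [0, 100], summing to 100; named with
#'   box labels.
#' @export
setClass("BoxVector",
    representation(
        sampleId = "character",
        pair = "character",
        nBins = "integer",
        percentages = "numeric"
    )
)

setValidity("BoxVector", function(object) {
    msg <- NULL
    b <- object@nBins
    if (length(b) != 1L || is.na(b) || b < 1L) {
        msg <- c(msg, "nBins must be a single integer >= 1")
    }
    if (length(object@pair) != 2L) {
        msg <- c(msg, "pair must hold exactly two marker names")
    }
    p <- object@percentages
    if (is.null(msg)) {
        if (length(p) != b * b) {
            msg <- c(msg, sprintf("percentages must have length b^2 = %d", b * b))
        } else if (abs(sum(p) - 100) > 1e-9) {
            msg <- c(msg, "percentages must sum to 100")
        } else if (any(p < 0 | p > 100)) {
            msg <- c(msg, "percentages must lie in [0, 100]")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' CalibrationResult: false-positive-rate estimates per bin number
#'
#' Holds, for each candidate bin number b, the estimated probability that a
#' linear support-vector classifier perfectly separates randomly relabeled
#' samples using the b^2 box-percentage features (the overfitting false
#' positive rate), plus the largest b whose estimate stays below the chosen
#' threshold.
#'
#' @slot entries data.frame with columns \code{b}, \code{fpr},
#'   \code{iterations}, sorted by \code{b}.
#' @slot recommendedB integer(1), largest safe bin number (>= 1).
#' @slot nSamples integer(1), cohort size used.
#' @slot threshold numeric(1), the FPR threshold applied.
#' @export
setClass("CalibrationResult",
    representation(
        entries = "data.frame",
        recommendedB = "integer",
        nSamples = "integer",
        threshold = "numeric"
    )
)

setValidity("CalibrationResult", function(object) {
    msg <- NULL
    e <- object@entries
    need <- c("b", "fpr", "iterations")
    if (!all(need %in% names(e))) {
        msg <- c(msg, "entries must have columns b, fpr, iterations")
    } else {
        if (is.unsorted(e$b, strictly = TRUE)) {
            msg <- c(msg, "entries must be sorted by strictly increasing b")
        }
        if (any(e$fpr < 0 | e$fpr > 1)) {
            msg <- c(msg, "fpr values must lie in [0, 1]")
        }
        if (any(e$iterations < 1)) {
            msg <- c(msg, "iterations must be >= 1")
        }
    }
    if (length(object@recommendedB) != 1L || object@recommendedB < 1L) {
        msg <- c(msg, "recommendedB must be a single integer >= 1")
    }
    if (is.null(msg)) TRUE else msg
})
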