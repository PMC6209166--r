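#' Equal-frequency percentile bin assignment
#'
#' Assigns each value to one of \code{b} equally populated bins, 1 = lowest
#' expression.  Assignment is rank-based with ties broken by original
#' position (stable): the cell at sorted position k (0-based) goes to bin
#' \code{floor(k * b / n) + 1}.  Every bin therefore holds \code{floor(n/b)}
#' or \code{ceiling(n/b)} cells regardless of ties — threshold-based
#' quantile cuts cannot guarantee this on the heavily tied intensity values
#' typical of cytometry data, which is why ranks are used.
#'
#' @param values numeric vector of per-cell intensities, length n >= b.
#' @param b integer, number of bins, >= 1.
#' @return integer vector of bin indices in 1..b, same length as
#'   \code{values}.
#' @examples
#' percentileBinIndices(c(1, 2, 3, 4, 5, 6), 3)
#' @export
percentileBinIndices <- function(values, b) {
    b <- as.integer(b)
    if (length(b) != 1L || is.na(b) || b < 1L) {
        stop("b must be a single integer >= 1")
    }
    n <- length(values)
    if (n < b) {
        stop("equal-frequency binning is undefined for n = ", n,
             " values and b = ", b, " bins (need n >= b)")
    }
    if (anyNA(values)) stop("values must not contain NA")
    bins <- integer(n)
    # order() is stable: ties keep original order, so bin occupancy is
    # forced to floor(n/b) or ceiling(n/b) even when all values are equal
    bins[order(values)] <- as.integer(((seq_len(n) - 1) * as.numeric(b)) %/% n) + 1L
    bins
}

#' Box labels for a given bin number
#'
#' A box (i, j) pairs bin i of the x-marker with bin j of the y-marker,
#' 1 = lowest expression.  The label reads "B{i}{j}" for b <= 9 and
#' "B{i}.{j}" otherwise; labels are emitted row-major with the x-marker bin
#' as the outer index, matching the straightened percentage vector.
#'
#' @param b integer, number of bins.
#' @return character vector of b^2 labels.
#' @examples
#' boxLabels(3)
#' @export
boxLabels <- function(b) {
    b <- as.integer(b)
    if (is.na(b) || b < 1L) stop("b must be an integer >= 1")
    i <- rep(seq_len(b), each = b)
    j <- rep(seq_len(b), times = b)
    if (b <= 9L) sprintf("B%d%d", i, j) else sprintf("B%d.%d", i, j)
}

#' Parse a box label into bin indices
#'
#' @param label character(1), e.g. "B32" or "B10.4".
#' @param b integer, number of bins the label refers to.
#' @return integer(2): c(i, j), the x- and y-marker bin indices.
#' @export
parseBoxLabel <- function(label, b) {
    b <- as.integer(b)
    idx <- match(label, boxLabels(b))
    if (is.na(idx)) {
        stop("'", label, "' is not a valid box label for b = ", b)
    }
    c(i = ((idx - 1L) %/% b) + 1L, j = ((idx - 1L) %% b) + 1L)
}

markerColumn <- function(sample, marker) {
    mk <- markerNames(sample)
    if (!marker %in% mk) {
        stop("marker '", marker, "' not found in sample '",
             sampleId(sample), "'; available: ",
             paste(mk, collapse = ", "))
    }
    intensities(sample)[, marker]
}

#' Box percentages of one marker pair
#'
#' Bins the two markers independently into \code{b} equal-frequency bins,
#' overlays the binnings into a b x b grid of boxes, and reports the
#' percentage of cells in each box — an estimate of the joint probability
#' P(A_i, B_j) of the two markers' bin levels.  The matrix is straightened
#' row-major (x-marker bin outer, y-marker bin inner) into a length-b^2
#' vector.
#'
#' @param sample a [CellSample-class].
#' @param pair character(2): x-marker then y-marker name.
#' @param b integer, number of bins; requires \code{nCells(sample) >= b}.
#' @return A [BoxVector-class].
#' @examples
#' cs <- cellSample(matrix(rnorm(600), 300, 2,
#'     dimnames = list(NULL, c("A", "B"))))
#' percentages(boxPercentages(cs, c("A", "B"), 3))
#' @export
boxPercentages <- function(sample, pair, b) {
    stopifnot(is(sample, "CellSample"))
    if (length(pair) != 2L) stop("pair must name exactly two markers")
    b <- as.integer(b)
    ix <- percentileBinIndices(markerColumn(sample, pair[1]), b)
    jy <- percentileBinIndices(markerColumn(sample, pair[2]), b)
    n <- nCells(sample)
    counts <- tabulate((ix - 1L) * b + jy, nbins = b * b)
    pct <- 100 * counts / n
    names(pct) <- boxLabels(b)
    new("BoxVector", sampleId = sampleId(sample),
        pair = as.character(pair), nBins = b, percentages = pct)
}

#' Median-centered log-ratio features from box vectors
#'
#' Box percentages are compositional (they sum to 100); to remove that
#' dependency each sample's vector is divided by its median before taking
#' log base 2.  Zero percentages are first replaced by half the smallest
#' positive percentage in the same vector, which keeps the transform finite
#' while preserving the ordering of boxes.  The median is taken after the
#' replacement (even length: mean of the two central order statistics).
#'
#' @param vectors a list of [BoxVector-class] objects sharing the same pair
#'   and bin number.
#' @return numeric matrix, samples x b^2 (rownames = sample ids, colnames =
#'   box labels), of log2 median-ratio features.
#' @export
logRatioFeatures <- function(vectors) {
    if (length(vectors) == 0L) stop("no box vectors supplied")
    stopifnot(all(vapply(vectors, is, logical(1), "BoxVector")))
    b <- nBins(vectors[[1]])
    feats <- vapply(vectors, function(v) {
        p <- percentages(v)
        if (stats::median(p) == 0) {
            stop("more than half of the ", length(p), " boxes of sample '",
                 sampleId(v), "' are empty; the median-ratio transform is ",
                 "degenerate -- use fewer bins")
        }
        p[p == 0] <- min(p[p > 0]) / 2
        log2(p / stats::median(p))
    }, numeric(b * b))
    feats <- if (is.null(dim(feats))) matrix(feats, ncol = 1L) else t(feats)
    rownames(feats) <- vapply(vectors, sampleId, character(1))
    colnames(feats) <- boxLabels(b)
    feats
}

#' Raw box-percentage feature table
#'
#' @param vectors list of [BoxVector-class] objects (same pair, same b).
#' @return numeric matrix, samples x b^2, of raw percentages.
#' @export
rawFeatures <- function(vectors) {
    if (length(vectors) == 0L) stop("no box vectors supplied")
    b <- nBins(vectors[[1]])
    feats <- vapply(vectors, percentages, numeric(b * b))
    feats <- if (is.null(dim(feats))) matrix(feats, ncol = 1L) else t(feats)
    rownames(feats) <- vapply(vectors, sampleId, character(1))
    colnames(feats) <- boxLabels(b)
    feats
}

#' Per-box mean intensity profile
#'
#' Selects the cells whose joint bin assignment for \code{pair} equals the
#' given box and reports, for every marker of the sample, their mean
#' intensity (MFI on the transformed scale).  Used to characterize what
#' cell type a discriminating box contains.
#'
#' @param sample a [CellSample-class].
#' @param pair character(2), x- then y-marker.
#' @param b integer bin number.
#' @param box box label string (e.g. "B32") or integer(2) c(i, j).
#' @return list with elements \code{box} (label), \code{i}, \code{j},
#'   \code{cellCount}, and \code{mfi} (named numeric over all markers;
#'   all-NA when the box is empty).
#' @export
boxProfile <- function(sample, pair, b, box) {
    stopifnot(is(sample, "CellSample"))
    b <- as.integer(b)
    if (is.character(box)) {
        ij <- parseBoxLabel(box, b)
    } else {
        ij <- as.integer(box)
        if (length(ij) != 2L || any(ij < 1L) || any(ij > b)) {
            stop("box indices must be two integers in 1..", b)
        }
    }
    ix <- percentileBinIndices(markerColumn(sample, pair[1]), b)
    jy <- percentileBinIndices(markerColumn(sample, pair[2]), b)
    inBox <- ix == ij[1] & jy == ij[2]
    label <- boxLabels(b)[(ij[1] - 1L) * b + ij[2]]
    if (!any(inBox)) {
        mfi <- rep(NA_real_, ncol(intensities(sample)))
        names(mfi) <- markerNames(sample)
    } else {
        mfi <- colMeans(intensities(sample)[inBox, , drop = FALSE])
    }
    list(box = label, i = ij[[1]], j = ij[[2]],
         cellCount = sum(inBox), mfi = mfi)
}

#' Enumerate analyzable marker pairs
#'
#' All unordered pairs of the cohort's markers in lexicographic order,
#' excluding blocklisted channels (e.g. a viability dye).  Within a pair the
#' x-marker is the lexicographically first name.
#'
#' @param markers character vector of marker names.
#' @param blocklist character vector of channels to exclude.
#' @return character matrix with columns \code{x} and \code{y}, one row per
#'   pair.
#' @examples
#' enumeratePairs(c("CD8", "CD3", "CCR7"))
#' @export
enumeratePairs <- function(markers, blocklist = character(0)) {
    markers <- sort(setdiff(unique(markers), blocklist))
    if (length(markers) < 2L) {
        stop("need at least two markers after applying the blocklist")
    }
    idx <- utils::combn(length(markers), 2L)
    cbind(x = markers[idx[1, ]], y = markers[idx[2, ]])
}

#' Box-percentage feature table for a whole cohort
#'
#' @param cohort list of [CellSample-class] objects sharing markers.
#' @param pair character(2).
#' @param b integer bin number.
#' @param logRatio logical: apply the median log-ratio transform (default)
#'   or return raw percentages.
#' @return samples x b^2 numeric matrix.
#' @export
cohortFeatures <- function(cohort, pair, b, logRatio = TRUE) {
    vecs <- lapply(cohort, boxPercentages, pair = pair, b = b)
    if (logRatio) logRatioFeatures(vecs) else rawFeatures(vecs)
}
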