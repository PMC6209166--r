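# Soft-margin linear SVM helper shared by the calibration and selection
# modules.  Features are standardized (zero mean, unit variance) before
# the fit, the conventional preprocessing for SVMs on box-percentage
# features whose variances differ by orders of magnitude across boxes;
# zero-variance features carry no class information and are dropped so the
# standardization stays well-defined.
fitLinearSVM <- function(x, y, C = 10) {
    y <- factor(y)
    if (nlevels(y) < 2L) {
        stop("training set contains a single class; cannot fit a classifier")
    }
    keep <- which(apply(x, 2, function(col) diff(range(col)) > 0))
    if (length(keep) == 0L) {
        # no variance anywhere: the classifier degenerates to majority vote
        return(list(fit = NULL, keep = keep))
    }
    fit <- suppressWarnings(kernlab::ksvm(
        x[, keep, drop = FALSE], y, type = "C-svc",
        kernel = kernlab::vanilladot(), C = C, scaled = TRUE
    ))
    list(fit = fit, keep = keep)
}

svmAccuracy <- function(model, x, y) {
    if (is.null(model$fit)) {
        return(max(table(y)) / length(y))
    }
    pred <- kernlab::predict(model$fit,
                             x[, model$keep, drop = FALSE],
                             type = "response")
    mean(pred == y)
}

#' Rule-of-thumb maximum number of bins
#'
#' The largest bin number that avoids overfitting grows with the number of
#' training samples: empirically, the maximum bin number with zero false
#' positive rate is about the square root of half the training-set size.
#'
#' @param nTraining integer, number of training samples (>= 2).
#' @return integer, \code{round(sqrt(nTraining / 2))} (round half up),
#'   at least 1.
#' @examples
#' maxBinsRule(46)  # 5
#' maxBinsRule(60)  # 5
#' @export
maxBinsRule <- function(nTraining) {
    nTraining <- as.numeric(nTraining)
    if (length(nTraining) != 1L || is.na(nTraining) || nTraining < 2) {
        stop("nTraining must be a single integer >= 2")
    }
    max(1L, as.integer(floor(sqrt(nTraining / 2) + 0.5)))
}

#' Estimate the overfitting false positive rate at one bin number
#'
#' The FPR of perfect classification under random relabeling: for each
#' marker pair, samples are repeatedly split uniformly at random into two
#' equal halves (ignoring their true group labels), a soft-margin linear
#' support-vector classifier (cost \code{C}) is fit on the b^2 log-ratio
#' box features, and the fraction of iterations in which the random
#' labeling is classified with 100\% training accuracy is recorded.  The
#' FPR estimate is the mean of that fraction over marker pairs.  A bin
#' number whose FPR exceeds the tolerance would let pure noise masquerade
#' as a perfectly discriminating marker pair.
#'
#' Training (resubstitution) accuracy is the relevant quantity here: it
#' measures the classifier's capacity to fit arbitrary labels at the given
#' feature dimension, which is exactly the overfitting risk being
#' calibrated.
#'
#' @param cohort list of [CellSample-class] objects; even length >= 4, all
#'   sharing the same markers.
#' @param b integer bin number.
#' @param iterations integer, number of random relabelings (default 100).
#' @param blocklist channels excluded from pair enumeration.
#' @param C soft-margin cost (default 10).
#' @param logRatio use log-ratio features (default) or raw percentages.
#' @return one-row data.frame with columns \code{b}, \code{fpr},
#'   \code{iterations}.
#' @export
estimateFPR <- function(cohort, b, iterations = 100L,
                        blocklist = character(0), C = 10,
                        logRatio = TRUE) {
    n <- length(cohort)
    if (n < 4L || n %% 2L != 0L) {
        stop("cohort size must be even and at least 4, got ", n)
    }
    b <- as.integer(b)
    iterations <- as.integer(iterations)
    if (iterations < 1L) stop("iterations must be >= 1")
    pairs <- enumeratePairs(markerNames(cohort[[1]]), blocklist)
    half <- n %/% 2L
    labels <- factor(rep(c("g1", "g2"), each = half))
    freq <- numeric(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
        feats <- cohortFeatures(cohort, pairs[p, ], b, logRatio = logRatio)
        hits <- 0L
        for (it in seq_len(iterations)) {
            perm <- sample.int(n)
            x <- feats[perm, , drop = FALSE]
            fit <- fitLinearSVM(x, labels, C = C)
            if (svmAccuracy(fit, x, labels) == 1) hits <- hits + 1L
        }
        freq[p] <- hits / iterations
    }
    data.frame(b = b, fpr = mean(freq), iterations = iterations)
}

#' False-positive-rate curve over candidate bin numbers
#'
#' Runs [estimateFPR()] for every bin number in \code{bList} and recommends
#' the largest b whose estimated FPR stays below \code{threshold}
#' (default 0.05; use 0 for the stringent zero-FPR criterion appropriate
#' when many marker pairs will be tested).
#'
#' @inheritParams estimateFPR
#' @param bList integer vector of candidate bin numbers.
#' @param threshold FPR threshold in [0, 1].
#' @return A [CalibrationResult-class].
#' @export
fprCurve <- function(cohort, bList = 2:8, iterations = 100L,
                     threshold = 0.05, blocklist = character(0),
                     C = 10, logRatio = TRUE) {
    if (length(bList) == 0L) stop("bList must not be empty")
    bList <- sort(unique(as.integer(bList)))
    entries <- do.call(rbind, lapply(bList, function(b) {
        estimateFPR(cohort, b, iterations = iterations,
                    blocklist = blocklist, C = C, logRatio = logRatio)
    }))
    safe <- entries$b[entries$fpr < threshold |
                          (threshold == 0 & entries$fpr == 0)]
    recommended <- if (length(safe)) max(safe) else 1L
    new("CalibrationResult",
        entries = entries,
        recommendedB = as.integer(recommended),
        nSamples = length(cohort),
        threshold = as.numeric(threshold))
}
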