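#' Split a labeled cohort into training and holdout sets
#'
#' Two modes are offered because cohorts rarely have equal group sizes:
#' \describe{
#'   \item{"strict"}{(default) holdout sizes are chosen per group so the two
#'     \emph{training} groups come out exactly equal: the smaller group
#'     gives up \code{ceiling(fraction * n_small)} samples and the larger
#'     group gives up that number plus its surplus.  Equal training groups
#'     are what the bin-number rule of thumb assumes.}
#'   \item{"proportional"}{each group gives up \code{floor(fraction * n_g)}
#'     samples (at least 1), leaving training groups in their original
#'     proportion.  With 34 + 22 samples and fraction 0.2 this yields a
#'     6 + 4 holdout and a 28 + 18 training set.}
#' }
#' Assignment within each group is uniform at random.
#'
#' @param cohort list of [CellSample-class] objects with exactly two
#'   distinct non-empty group labels.
#' @param fraction approximate holdout fraction of the cohort, in (0, 1).
#' @param mode "strict" or "proportional".
#' @return list with elements \code{train} and \code{holdout}, each a list
#'   of samples.
#' @export
balancedSplit <- function(cohort, fraction = 0.2, mode = c("strict",
                          "proportional")) {
    mode <- match.arg(mode)
    if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
    groups <- cohortGroups(cohort)
    if (any(!nzchar(groups))) stop("all samples must carry a group label")
    lv <- unique(groups)
    if (length(lv) != 2L) {
        stop("cohort must contain exactly two groups, found: ",
             paste(lv, collapse = ", "))
    }
    nG <- c(sum(groups == lv[1]), sum(groups == lv[2]))
    small <- which.min(nG); large <- 3L - small
    hold <- integer(2)
    if (mode == "strict") {
        hold[small] <- max(1L, as.integer(ceiling(fraction * nG[small])))
        hold[large] <- hold[small] + (nG[large] - nG[small])
        if (hold[large] >= nG[large] || hold[small] >= nG[small]) {
            stop("cannot equalize training groups: would need a holdout of ",
                 hold[large], " from the larger group (", nG[large],
                 " samples) and ", hold[small], " from the smaller (",
                 nG[small], "); reduce the imbalance or use mode = ",
                 "'proportional'")
        }
    } else {
        hold <- pmax(1L, as.integer(floor(fraction * nG)))
        if (any(hold >= nG)) {
            stop("holdout would exhaust a group (sizes ", nG[1], " + ",
                 nG[2], ", holdout ", hold[1], " + ", hold[2], ")")
        }
    }
    holdIdx <- unlist(lapply(1:2, function(g) {
        idx <- which(groups == lv[g])
        sample(idx, hold[g])
    }))
    list(train = cohort[-holdIdx], holdout = cohort[holdIdx])
}

#' Evaluate one marker pair's ability to discriminate the groups
#'
#' Fits a soft-margin linear support-vector classifier (cost \code{C}) on
#' the training samples' log-ratio box features for the pair and scores it
#' on both the training and the holdout samples.  A pair is selected when
#' both accuracies are exactly 1 — box features at \code{b} bins then carry
#' enough information to separate the groups perfectly and the separation
#' generalizes to unseen samples.
#'
#' @param train,holdout lists of labeled [CellSample-class] objects.
#' @param pair character(2), x- then y-marker.
#' @param b integer bin number (typically [maxBinsRule()] of the training
#'   size).
#' @param C soft-margin cost (default 10).
#' @param logRatio use log-ratio features (default) or raw percentages.
#' @return one-row data.frame: \code{markerX}, \code{markerY}, \code{b},
#'   \code{trainAccuracy}, \code{testAccuracy}, \code{selected}.
#' @export
evaluatePair <- function(train, holdout, pair, b, C = 10, logRatio = TRUE) {
    yTrain <- factor(cohortGroups(train))
    if (nlevels(yTrain) < 2L) {
        stop("training set contains a single group")
    }
    xTrain <- cohortFeatures(train, pair, b, logRatio = logRatio)
    fit <- fitLinearSVM(xTrain, yTrain, C = C)
    trainAcc <- svmAccuracy(fit, xTrain, yTrain)
    if (length(holdout)) {
        xTest <- cohortFeatures(holdout, pair, b, logRatio = logRatio)
        yTest <- factor(cohortGroups(holdout), levels = levels(yTrain))
        testAcc <- svmAccuracy(fit, xTest, yTest)
    } else {
        testAcc <- NA_real_
    }
    data.frame(markerX = pair[1], markerY = pair[2], b = as.integer(b),
               trainAccuracy = trainAcc, testAccuracy = testAcc,
               selected = isTRUE(trainAcc == 1 && testAcc == 1))
}

#' Screen all marker pairs for perfect group discrimination
#'
#' Enumerates every unordered marker pair (minus the blocklist), evaluates
#' each with [evaluatePair()] on one shared training/holdout split, and
#' returns the results sorted by selection flag, test accuracy, then pair
#' name.  One shared split is used for all pairs so that selected pairs are
#' comparable.
#'
#' @param cohort labeled cohort (list of [CellSample-class]).
#' @param b integer bin number, or \code{"auto"} to apply [maxBinsRule()]
#'   to the training-set size.
#' @param fraction,mode passed to [balancedSplit()].
#' @param blocklist channels excluded from enumeration (e.g. viability dye).
#' @param C,logRatio passed to [evaluatePair()].
#' @return data.frame, one row per pair, columns as in [evaluatePair()].
#'   The split is attached as attribute \code{"split"} and the resolved
#'   bin number as attribute \code{"b"}.
#' @export
selectPairs <- function(cohort, b = "auto", fraction = 0.2,
                        mode = "strict", blocklist = character(0),
                        C = 10, logRatio = TRUE) {
    split <- balancedSplit(cohort, fraction = fraction, mode = mode)
    if (identical(b, "auto")) {
        b <- maxBinsRule(length(split$train))
    }
    b <- as.integer(b)
    pairs <- enumeratePairs(markerNames(cohort[[1]]), blocklist)
    res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
        evaluatePair(split$train, split$holdout, pairs[p, ], b,
                     C = C, logRatio = logRatio)
    }))
    res <- res[order(-res$selected, -res$testAccuracy,
                     res$markerX, res$markerY), ]
    rownames(res) <- NULL
    attr(res, "split") <- split
    attr(res, "b") <- b
    res
}
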