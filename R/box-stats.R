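#' Two-sided Mann-Whitney U test p-value
#'
#' Thin, explicit wrapper around the rank-sum test used for all box
#' comparisons: the exact null distribution of U is used whenever the
#' smaller sample has at most 25 observations and there are no ties
#' (two-sided p = twice the smaller tail, capped at 1); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.  With complete separation of two groups of 10 the exact two-sided
#' p is 2 / choose(20, 10), about 1.08e-5 — the floor any box test can
#' reach at that cohort size.
#'
#' @param x,y numeric vectors, each of length >= 1.
#' @return two-sided p-value in (0, 1].
#' @examples
#' mannWhitneyP(1:3, 4:6)  # 2 / choose(6, 3) = 0.1
#' @export
mannWhitneyP <- function(x, y) {
    if (length(x) < 1L || length(y) < 1L) {
        stop("both samples must contain at least one observation")
    }
    if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && min(length(x), length(y)) <= 25L
    suppressWarnings(stats::wilcox.test(
        x, y, alternative = "two.sided", exact = exact, correct = TRUE
    ))$p.value
}

#' Test every box of the selected marker pairs for group differences
#'
#' For each selected pair, the per-sample box percentages (raw, not
#' log-ratio: rank tests are invariant to the monotone transform, and
#' percentages are the interpretable scale) are compared between the two
#' groups box by box with [mannWhitneyP()].  All boxes of all selected
#' pairs form a single Bonferroni family of size
#' \code{nrow(selectedPairs) * b^2}; a box is significant when its adjusted
#' p falls below \code{alpha}.  Pairs that contribute no significant box
#' are pruned from the selection (their rows remain in the output, flagged
#' by \code{pairRetained}).
#'
#' @param cohort labeled cohort (list of [CellSample-class] with two
#'   groups).
#' @param selectedPairs data.frame with columns \code{markerX},
#'   \code{markerY} (e.g. the selected rows of [selectPairs()] output).
#' @param b integer bin number.
#' @param alpha significance level on the adjusted p (default 0.001).
#' @param adjust "bonferroni" (default) or "BH".
#' @return data.frame with one row per box: \code{markerX}, \code{markerY},
#'   \code{box}, \code{i}, \code{j}, group medians, \code{rawP},
#'   \code{adjustedP}, \code{significant}, \code{direction} (group with
#'   the larger median), \code{medianDiff} (absolute difference of the
#'   group medians, the tie-breaker when exact p-values saturate), and
#'   \code{pairRetained}.  Rows are ordered by adjusted p, then effect
#'   size.
#' @export
importantBoxes <- function(cohort, selectedPairs, b, alpha = 0.001,
                           adjust = c("bonferroni", "BH")) {
    adjust <- match.arg(adjust)
    if (NROW(selectedPairs) < 1L) {
        stop("at least one selected marker pair is required")
    }
    if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
    b <- as.integer(b)
    groups <- cohortGroups(cohort)
    lv <- unique(groups)
    if (length(lv) != 2L) stop("cohort must contain exactly two groups")
    res <- do.call(rbind, lapply(seq_len(NROW(selectedPairs)), function(p) {
        pair <- c(selectedPairs$markerX[p], selectedPairs$markerY[p])
        feats <- cohortFeatures(cohort, pair, b, logRatio = FALSE)
        labels <- boxLabels(b)
        do.call(rbind, lapply(seq_len(b * b), function(k) {
            v1 <- feats[groups == lv[1], k]
            v2 <- feats[groups == lv[2], k]
            m1 <- stats::median(v1); m2 <- stats::median(v2)
            data.frame(
                markerX = pair[1], markerY = pair[2], box = labels[k],
                i = ((k - 1L) %/% b) + 1L, j = ((k - 1L) %% b) + 1L,
                median1 = m1, median2 = m2,
                rawP = mannWhitneyP(v1, v2)
            )
        }))
    }))
    names(res)[names(res) == "median1"] <- paste0("median_", lv[1])
    names(res)[names(res) == "median2"] <- paste0("median_", lv[2])
    res$adjustedP <- stats::p.adjust(res$rawP, method = adjust)
    res$significant <- res$adjustedP < alpha
    m1 <- res[[paste0("median_", lv[1])]]
    m2 <- res[[paste0("median_", lv[2])]]
    res$direction <- ifelse(m1 > m2, lv[1], ifelse(m2 > m1, lv[2], "tie"))
    res$medianDiff <- abs(m1 - m2)
    pairKey <- paste(res$markerX, res$markerY, sep = "|")
    keep <- unique(pairKey[res$significant])
    res$pairRetained <- pairKey %in% keep
    # the exact rank test saturates at its floor under complete separation,
    # so ties on adjusted p are broken by effect size (median difference)
    res <- res[order(res$adjustedP, -res$medianDiff, res$box), ]
    rownames(res) <- NULL
    attr(res, "familySize") <- NROW(selectedPairs) * b * b
    attr(res, "alpha") <- alpha
    res
}
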