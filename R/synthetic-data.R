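#' Synthetic two-marker point patterns
#'
#' Generators for two classes of synthetic point patterns used to exercise
#' and calibrate the binning pipeline.  Both patterns share two large
#' isotropic Gaussian clusters of 5,000 points each, centered at (0, 4) and
#' (0, -4) with standard deviation 2.  They differ only in a third, smaller
#' cluster:
#' \describe{
#'   \item{pattern A}{third cluster at (4, 0), sd 1, holding 10--20\% of all
#'     cells (a uniformly drawn count in 1112..2500);}
#'   \item{pattern B}{third cluster at (-4, 6), sd 1, holding only 200--500
#'     points (about 2--5\% of all cells).}
#' }
#' The third clusters emulate a moderately abundant and a rare cell
#' sub-population whose frequency differs between two donor groups.  Draws
#' use the session RNG; seed with [set.seed()] (or use [makeCohort()], which
#' manages per-sample seeds) for reproducibility.
#'
#' @param sampleId character(1) identifier for the generated sample.
#' @param groupLabel character(1) group label (defaults "A"/"B").
#' @param markerNames character(2), names for the two virtual markers.
#' @return A [CellSample-class] with an attribute \code{"clusterSizes"}
#'   (integer(3), points per cluster in generation order).
#' @examples
#' set.seed(1)
#' a <- makePatternA()
#' nCells(a)
#' @name patterns
NULL

rclust <- function(n, center, sd) {
    cbind(stats::rnorm(n, center[1], sd), stats::rnorm(n, center[2], sd))
}

makePattern <- function(third, sampleId, groupLabel, markerNames) {
    sizes <- c(5000L, 5000L, third$count)
    pts <- rbind(
        rclust(sizes[1], c(0, 4), 2),
        rclust(sizes[2], c(0, -4), 2),
        rclust(sizes[3], third$center, third$sd)
    )
    colnames(pts) <- markerNames
    out <- cellSample(pts, sampleId = sampleId, groupLabel = groupLabel)
    attr(out, "clusterSizes") <- sizes
    out
}

#' @rdname patterns
#' @export
makePatternA <- function(sampleId = "A1", groupLabel = "A",
                         markerNames = c("markerA", "markerB")) {
    # uniform count in 1112..2500 puts the third cluster at exactly
    # 10-20% of the total (1112/11112 = 0.100, 2500/12500 = 0.200)
    count <- sample(1112:2500, 1L)
    makePattern(list(center = c(4, 0), sd = 1, count = count),
                sampleId, groupLabel, markerNames)
}

#' @rdname patterns
#' @export
makePatternB <- function(sampleId = "B1", groupLabel = "B",
                         markerNames = c("markerA", "markerB")) {
    count <- sample(200:500, 1L)
    makePattern(list(center = c(-4, 6), sd = 1, count = count),
                sampleId, groupLabel, markerNames)
}

# Deterministic, splittable child-seed derivation: a small multiplicative
# hash of (masterSeed, group index, sample index) folded into [0, 2^31).
# Adding samples or groups never perturbs the seeds of earlier ones.
childSeed <- function(masterSeed, groupIndex, sampleIndex) {
    h <- (as.numeric(masterSeed) %% 2147483647) + 0
    for (k in c(groupIndex, sampleIndex)) {
        h <- (h * 69069 + 1234567 + 97 * k) %% 2147483647
    }
    as.integer(h)
}

#' Generate a labeled two-group cohort of synthetic samples
#'
#' Draws \code{nPerGroup[1]} samples from the first pattern generator and
#' \code{nPerGroup[2]} from the second, each from its own deterministic
#' child seed derived from \code{masterSeed}, so cohorts are exactly
#' reproducible and extending a cohort never changes existing samples.
#'
#' @param nPerGroup integer(2) (or integer(1), recycled): samples per group.
#' @param masterSeed integer master seed.
#' @param patterns list of two generator functions taking
#'   \code{(sampleId, groupLabel)}; default pattern A vs pattern B.
#'   Pass the same generator twice for a null (no-difference) cohort.
#' @param groupLabels character(2) group names.
#' @param extraMarkers integer, number of additional independent N(0, 1)
#'   noise markers appended to every sample (named "noise1", ...);
#'   useful for testing pair selection among uninformative markers.
#' @return list of [CellSample-class] objects, first group then second.
#' @examples
#' cohort <- makeCohort(c(2, 2), masterSeed = 7)
#' vapply(cohort, groupLabel, character(1))
#' @export
makeCohort <- function(nPerGroup = c(10L, 10L), masterSeed = 1L,
                       patterns = list(makePatternA, makePatternB),
                       groupLabels = c("A", "B"),
                       extraMarkers = 0L) {
    nPerGroup <- rep_len(as.integer(nPerGroup), 2L)
    stopifnot(all(nPerGroup >= 1L), length(patterns) == 2L,
              length(groupLabels) == 2L)
    if (groupLabels[1] == groupLabels[2]) {
        stop("the two group labels must be distinct")
    }
    cohort <- list()
    for (g in 1:2) {
        for (s in seq_len(nPerGroup[g])) {
            set.seed(childSeed(masterSeed, g, s))
            smp <- patterns[[g]](sampleId = paste0(groupLabels[g], s),
                                 groupLabel = groupLabels[g])
            if (extraMarkers > 0L) {
                noise <- matrix(stats::rnorm(nCells(smp) * extraMarkers),
                                ncol = extraMarkers)
                colnames(noise) <- paste0("noise", seq_len(extraMarkers))
                smp <- cellSample(cbind(intensities(smp), noise),
                                  sampleId = sampleId(smp),
                                  groupLabel = groupLabel(smp))
            }
            cohort[[length(cohort) + 1L]] <- smp
        }
    }
    cohort
}

#' Group labels of a cohort
#'
#' @param cohort list of [CellSample-class] objects.
#' @return character vector of per-sample group labels.
#' @export
cohortGroups <- function(cohort) {
    vapply(cohort, groupLabel, character(1))
}
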