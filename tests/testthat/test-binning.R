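test_that("percentileBinIndices splits sorted distinct values equally", {
    expect_equal(percentileBinIndices(c(1, 2, 3, 4, 5, 6), 3),
                 c(1L, 1L, 2L, 2L, 3L, 3L))
    expect_equal(percentileBinIndices(c(6, 5, 4, 3, 2, 1), 3),
                 c(3L, 3L, 2L, 2L, 1L, 1L))
    expect_equal(percentileBinIndices(c(5), 1), 1L)
})

test_that("bin occupancy is floor(n/b) or ceiling(n/b) even under heavy ties", {
    # all-equal values: the stable tie rule forces equal bins in input order
    expect_equal(percentileBinIndices(rep(7, 9), 3), rep(1:3, each = 3))
    for (seed in 1:10) {
        set.seed(seed)
        n <- sample(10:200, 1)
        b <- sample(2:min(9, n), 1)
        vals <- sample(round(rnorm(n), sample(0:1, 1)))  # many ties
        counts <- tabulate(percentileBinIndices(vals, b), nbins = b)
        expect_true(all(counts %in% c(floor(n / b), ceiling(n / b))),
                    info = sprintf("seed %d n %d b %d", seed, n, b))
        expect_equal(sum(counts), n)
    }
})

test_that("bin assignment is invariant under strictly monotone transforms", {
    set.seed(4)
    vals <- c(rnorm(80), rep(0.5, 20))
    for (b in c(2, 3, 5)) {
        ref <- percentileBinIndices(vals, b)
        expect_equal(percentileBinIndices(exp(vals), b), ref)
        expect_equal(percentileBinIndices(2 * vals + 10, b), ref)
        expect_equal(percentileBinIndices(atan(vals), b), ref)
    }
})

test_that("binning errors are informative", {
    expect_error(percentileBinIndices(1:3, 5), "undefined")
    expect_error(percentileBinIndices(1:3, 0), "b must be")
    expect_error(percentileBinIndices(c(1, NA, 3), 2), "NA")
})

test_that("boxPercentages produces b^2 percentages summing to 100", {
    cs <- tinySample("s1", "G1", n = 121, seed = 5)
    for (b in c(1, 2, 3, 5)) {
        bv <- boxPercentages(cs, c("m1", "m2"), b)
        expect_length(percentages(bv), b^2)
        expect_equal(sum(percentages(bv)), 100, tolerance = 1e-12)
        expect_equal(names(percentages(bv)), boxLabels(b))
        # marginal equal-frequency guarantee up to integer divisibility
        p <- matrix(percentages(bv), nrow = b, byrow = TRUE)
        n <- nCells(cs)
        lim <- c(floor(n / b), ceiling(n / b)) * 100 / n
        expect_true(all(rowSums(p) >= lim[1] - 1e-9 &
                            rowSums(p) <= lim[2] + 1e-9))
        expect_true(all(colSums(p) >= lim[1] - 1e-9 &
                            colSums(p) <= lim[2] + 1e-9))
    }
    expect_error(boxPercentages(cs, c("m1", "nope"), 3), "nope")
})

test_that("perfectly correlated markers fill only the diagonal boxes", {
    x <- rnorm(90)
    cs <- cellSample(cbind(m1 = x, m2 = x), sampleId = "d")
    p <- matrix(percentages(boxPercentages(cs, c("m1", "m2"), 3)),
                nrow = 3, byrow = TRUE)
    expect_equal(diag(p), rep(100 / 3, 3), tolerance = 1e-9)
    expect_equal(sum(p) - sum(diag(p)), 0)
})

test_that("the planted cluster of pattern A lands in box B32 at b = 3", {
    a <- sharedCohort20[[1]]
    bv <- boxPercentages(a, sharedPair, 3)
    p <- percentages(bv)
    frac <- p[["B32"]] / 100
    expect_gt(frac, 0.10)
    expect_lt(frac, 0.25)
    # B32 is the largest box by a clear margin
    expect_equal(names(which.max(p)), "B32")
})

test_that("box labels and parsing agree in both direction and format", {
    expect_equal(boxLabels(3)[1:4], c("B11", "B12", "B13", "B21"))
    expect_equal(parseBoxLabel("B32", 3), c(i = 3L, j = 2L))
    expect_equal(parseBoxLabel("B10.4", 10), c(i = 10L, j = 4L))
    expect_error(parseBoxLabel("B44", 3), "not a valid box label")
})

test_that("log-ratio features follow the median-ratio definition", {
    mkvec <- function(p) new("BoxVector", sampleId = "s",
                             pair = c("a", "b"),
                             nBins = as.integer(sqrt(length(p))),
                             percentages = p)
    # hand arithmetic: [10,20,40,30]/median(25) -> log2 c(.4,.8,1.6,1.2)
    f <- logRatioFeatures(list(mkvec(c(10, 20, 40, 30))))
    expect_equal(as.vector(f), log2(c(10, 20, 40, 30) / 25))
    # all-equal percentages map to all zeros
    f0 <- logRatioFeatures(list(mkvec(rep(25, 4))))
    expect_equal(as.vector(f0), rep(0, 4))
    # scale invariance of the ratio: relative composition is what matters
    v1 <- c(10, 20, 30, 40)
    f1 <- logRatioFeatures(list(mkvec(v1)))
    expect_equal(as.vector(f1), log2(v1 / stats::median(v1)))
    # zero replacement by half the smallest positive value
    v2 <- c(0, 10, 40, 50)
    f2 <- logRatioFeatures(list(mkvec(v2)))
    expect_equal(f2[1, 1], log2(5 / stats::median(c(5, 10, 40, 50))))
    # degenerate: more than half the boxes empty
    v3 <- c(60, 40, 0, 0, 0, 0, 0, 0, 0)
    expect_error(logRatioFeatures(list(mkvec(v3))), "fewer bins")
})

test_that("boxProfile reports per-box mean intensities", {
    cs <- tinySample("s1", "G1", n = 90, seed = 9, nMarkers = 3)
    # b = 1: the single box holds every cell
    pr <- boxProfile(cs, c("m1", "m2"), 1, "B11")
    expect_equal(pr$cellCount, 90)
    expect_equal(pr$mfi, colMeans(intensities(cs)))
    # empty box: perfectly correlated markers leave off-diagonals empty
    x <- rnorm(60)
    cor2 <- cellSample(cbind(m1 = x, m2 = x), sampleId = "c")
    pr2 <- boxProfile(cor2, c("m1", "m2"), 3, "B13")
    expect_equal(pr2$cellCount, 0)
    expect_true(all(is.na(pr2$mfi)))
    expect_error(boxProfile(cs, c("m1", "m2"), 3, c(4, 1)), "1..3")
})

test_that("pattern A's B32 profile recovers the planted cluster center", {
    a <- sharedCohort20[[1]]
    pr <- boxProfile(a, sharedPair, 3, "B32")
    expect_gt(pr$cellCount, 1000)
    # cluster at (4, 0) with sd 1; box admixture shifts means slightly
    expect_equal(unname(pr$mfi["markerA"]), 4, tolerance = 0.15)
    expect_equal(unname(pr$mfi["markerB"]), 0, tolerance = 0.3)
})

test_that("pair enumeration is lexicographic and honors the blocklist", {
    p <- enumeratePairs(c("CD8", "CD3", "CCR7"))
    expect_equal(nrow(p), 3)
    expect_equal(p[1, ], c(x = "CCR7", y = "CD3"))
    markers16 <- c(paste0("mk", sprintf("%02d", 1:15)), "LiveDead")
    p2 <- enumeratePairs(markers16, blocklist = "LiveDead")
    expect_equal(nrow(p2), choose(15, 2))   # 105
    expect_false(any(p2 == "LiveDead"))
    expect_error(enumeratePairs("one"), "at least two markers")
})

test_that("mean box percentage approaches 100/b^2 for independent markers", {
    set.seed(21)
    cs <- cellSample(cbind(m1 = runif(20000), m2 = runif(20000)),
                     sampleId = "u")
    for (b in c(3, 5)) {
        p <- percentages(boxPercentages(cs, c("m1", "m2"), b))
        expect_equal(mean(p), 100 / b^2, tolerance = 1e-12)
        expect_lt(max(abs(p - 100 / b^2)), 5 * sqrt(100 / b^2))
    }
})
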