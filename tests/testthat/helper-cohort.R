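# Shared synthetic cohorts, generated once per test run.  Master seeds are
# fixed so every test sees the same cohorts.
sharedCohort20 <- makeCohort(c(10, 10), masterSeed = 11)
sharedPair <- c("markerA", "markerB")

# small cheap cohort for structural tests that do not need realistic sizes
tinySample <- function(id, group, n = 60, seed = 1, nMarkers = 2) {
    set.seed(seed)
    m <- matrix(rnorm(n * nMarkers), ncol = nMarkers)
    colnames(m) <- paste0("m", seq_len(nMarkers))
    cellSample(m, sampleId = id, groupLabel = group)
}

tinyCohort <- function(nPerGroup = c(5, 5), n = 60, nMarkers = 2) {
    out <- list()
    k <- 0
    for (g in 1:2) {
        for (s in seq_len(nPerGroup[g])) {
            k <- k + 1
            out[[k]] <- tinySample(paste0("g", g, "s", s), paste0("G", g),
                                   n = n, seed = 100 * g + s,
                                   nMarkers = nMarkers)
        }
    }
    out
}

# independent brute-force oracle for the two-sided Mann-Whitney p-value:
# enumerate every assignment of the pooled observations to the two groups,
# compute the U statistic for each, and double the smaller tail
bruteForceMannWhitneyP <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    N <- length(pooled)
    r <- rank(pooled)
    uOf <- function(idx) sum(r[idx]) - n * (n + 1) / 2
    uObs <- uOf(seq_len(n))
    us <- utils::combn(N, n, uOf)
    pLow <- mean(us <= uObs)
    pHigh <- mean(us >= uObs)
    min(1, 2 * min(pLow, pHigh))
}
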