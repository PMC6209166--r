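test_that("a float32 FCS fixture round-trips through readFCS", {
    mat <- randomEventMatrix(100, c("FSC-A", "SSC-A", "FL1-A"), seed = 2)
    path <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path, mat)
    cs <- readFCS(path)
    expect_s4_class(cs, "CellSample")
    expect_equal(dim(intensities(cs)), c(100L, 3L))
    expect_equal(markerNames(cs), colnames(mat))
    expect_equal(unname(intensities(cs)), unname(mat), tolerance = 1e-6)
})

test_that("stain names ($PnS) take precedence and subsets are honored", {
    mat <- randomEventMatrix(50, c("FL1-A", "FL2-A", "Time"), seed = 3)
    path <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path, mat, stainNames = c("CD8", "CCR7", ""))
    cs <- readFCS(path)
    expect_equal(markerNames(cs), c("CD8", "CCR7", "Time"))
    sub <- readFCS(path, markerSubset = c("CCR7", "CD8"))
    expect_equal(markerNames(sub), c("CCR7", "CD8"))
    expect_error(readFCS(path, markerSubset = "CD4"),
                 "available channels.*CD8")
})

test_that("double, integer and big-endian encodings decode identically", {
    mat <- randomEventMatrix(40, c("a", "b"), seed = 4)
    imat <- matrix(as.integer(round(mat)), ncol = 2,
                   dimnames = dimnames(mat))
    for (spec in list(list(dt = "D", en = "little", m = mat, tol = 1e-12),
                      list(dt = "F", en = "big", m = mat, tol = 1e-6),
                      list(dt = "I", en = "little", m = imat, tol = 0),
                      list(dt = "I", en = "big", m = imat, tol = 0))) {
        path <- withr::local_tempfile(fileext = ".fcs")
        writeSyntheticFCS(path, spec$m, datatype = spec$dt,
                          endian = spec$en)
        cs <- readFCS(path)
        expect_equal(unname(intensities(cs)), unname(spec$m * 1),
                     tolerance = spec$tol,
                     info = paste(spec$dt, spec$en))
    }
})

test_that("malformed FCS files fail with named format errors", {
    mat <- randomEventMatrix(30, c("a", "b"))
    path <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path, mat)
    # truncate inside the DATA segment
    raw <- readBin(path, "raw", file.size(path))
    trunc <- withr::local_tempfile(fileext = ".fcs")
    writeBin(raw[1:(length(raw) - 50)], trunc)
    expect_error(readFCS(trunc), "truncated")
    # missing $TOT keyword
    path2 <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path2, mat, dropTot = TRUE)
    expect_error(readFCS(path2), "\\$TOT")
    # not an FCS file at all
    txt <- withr::local_tempfile()
    writeLines(strrep("this is not list-mode cytometry data at all; ", 4),
               txt)
    expect_error(readFCS(txt), "version")
    # duplicate stain names violate marker uniqueness
    path3 <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path3, mat, stainNames = c("CD3", "CD3"))
    expect_error(readFCS(path3), "not unique")
})

test_that("an embedded spill matrix is recovered and inverts correctly", {
    set.seed(8)
    true <- matrix(rnorm(15 * 2, sd = 2), ncol = 2,
                   dimnames = list(NULL, c("FL1", "FL2")))
    spill <- matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE,
                    dimnames = list(c("FL1", "FL2"), c("FL1", "FL2")))
    observed <- true %*% spill
    path <- withr::local_tempfile(fileext = ".fcs")
    writeSyntheticFCS(path, observed, datatype = "D", spill = spill)
    cs <- readFCS(path)
    expect_equal(attr(cs, "spill"), spill)
    comp <- applyCompensation(cs)
    expect_equal(unname(intensities(comp)), unname(true),
                 tolerance = 1e-9)
})

test_that("compensation solves the linear system and validates inputs", {
    cs <- cellSample(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
                            dimnames = list(NULL, c("x", "y"))))
    spill <- matrix(c(1, 0.1, 0, 1), 2, 2, byrow = TRUE,
                    dimnames = list(c("x", "y"), c("x", "y")))
    comp <- applyCompensation(cs, spill)
    # hand-solved unmixing: [t1, t2] %*% spill = [o1, o2]
    # so t1 = o1 and t2 = o2 - 0.1 * o1
    o <- intensities(cs)
    expect_equal(intensities(comp)[, "x"], o[, "x"])
    expect_equal(intensities(comp)[, "y"], o[, "y"] - 0.1 * o[, "x"])
    # identity spill is the identity operation
    id <- diag(2); dimnames(id) <- dimnames(spill)
    expect_equal(intensities(applyCompensation(cs, id)), o)
    # untouched markers pass through unchanged
    cs3 <- cellSample(cbind(o, z = c(7, 8, 9)))
    comp3 <- applyCompensation(cs3, spill)
    expect_equal(intensities(comp3)[, "z"], c(7, 8, 9))
    # singular spill
    bad <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                  dimnames = dimnames(spill))
    expect_error(applyCompensation(cs, bad), "singular")
    # unknown labels
    miss <- spill; dimnames(miss) <- list(c("x", "q"), c("x", "q"))
    expect_error(applyCompensation(cs, miss), "q")
    expect_error(applyCompensation(cs, spill = NULL), "no spill")
})

test_that("text matrices round-trip losslessly with sidecar metadata", {
    cs <- tinySample("donor-07", "old", n = 200, seed = 6, nMarkers = 4)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCellMatrix(cs, path)
    back <- readCellMatrix(path)
    expect_equal(sampleId(back), "donor-07")
    expect_equal(groupLabel(back), "old")
    expect_equal(markerNames(back), markerNames(cs))
    expect_equal(intensities(back), intensities(cs), tolerance = 1e-8)
    # a second round trip is bitwise stable at the printed precision
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeCellMatrix(back, path2)
    expect_identical(intensities(readCellMatrix(path2)),
                     intensities(back))
})

test_that("a wide high-count matrix survives the text round trip", {
    set.seed(10)
    big <- cellSample(matrix(rnorm(20000 * 41), ncol = 41,
                             dimnames = list(NULL, paste0("mk", 1:41))),
                      sampleId = "big")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCellMatrix(big, path)
    back <- readCellMatrix(path)
    expect_equal(dim(intensities(back)), c(20000L, 41L))
    expect_equal(intensities(back), intensities(big), tolerance = 1e-8)
})

test_that("text format errors carry the offending line", {
    empty <- withr::local_tempfile()
    file.create(empty)
    expect_error(readCellMatrix(empty), "format error")
    ragged <- withr::local_tempfile()
    writeLines(c("# sample_id: r", "# group_label: ", "m1\tm2",
                 "1\t2", "3\t4\t5", "6\t7"), ragged)
    expect_error(readCellMatrix(ragged), "line 5")
    alpha <- withr::local_tempfile()
    writeLines(c("m1\tm2", "1\ttwo"), alpha)
    expect_error(readCellMatrix(alpha), "non-numeric")
})
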