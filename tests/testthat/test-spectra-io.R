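test_that("wide CSV round-trips shape, axis order and exact intensities", {
    path <- withr::local_tempfile(fileext = ".csv")
    set.seed(1)
    axis <- c(100, 150, 220, 300, 410)          # non-uniform on purpose
    m <- matrix(runif(15, 0, 1000), nrow = 3)
    ds <- SpectralDataset(m, shift = axis,
                          sampleIds = c("A", "B", "C"),
                          replicateIds = c("1", "1", "2"))
    writeSpectraTable(ds, path, layout = "wide")
    back <- readSpectraTable(path, layout = "wide")
    expect_equal(dim(intensityMatrix(back)), c(3L, 5L))
    expect_identical(shiftAxis(back), axis)
    expect_identical(unname(intensityMatrix(back)), m)   # bit-exact
    expect_identical(back$sample_id, c("A", "B", "C"))
    expect_identical(back$replicate_id, c("1", "1", "2"))
})

test_that("long layout reads the same data as wide", {
    pw <- withr::local_tempfile(fileext = ".csv")
    pl <- withr::local_tempfile(fileext = ".csv")
    ds <- makeTinyDataset()
    writeSpectraTable(ds, pw, "wide")
    writeSpectraTable(ds, pl, "long")
    expect_identical(intensityMatrix(readSpectraTable(pl, "long")),
                     intensityMatrix(readSpectraTable(pw, "wide")))
})

test_that("a descending-axis file is reversed consistently", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("shift,S1", "300,3", "200,2", "100,1"), path)
    ds <- readSpectraTable(path, "wide")
    expect_identical(shiftAxis(ds), c(100, 200, 300))
    expect_identical(as.numeric(intensityMatrix(ds)), c(1, 2, 3))
})

test_that("non-monotone or duplicated axes are format errors", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("shift,S1", "100,1", "300,2", "200,3"), path)
    expect_error(readSpectraTable(path, "wide"), "not monotone")
    writeLines(c("shift,S1", "100,1", "100,2", "200,3"), path)
    expect_error(readSpectraTable(path, "wide"), "duplicated")
})

test_that("a ~0.964 cm^-1 axis over 50-3398 yields 3473 accepted channels", {
    # spacing implied by the largest spectral-variable count of the
    # full-range design: (3398 - 50) / 3472 = 0.9643 cm^-1
    axis <- seq(50, 3398, length.out = 3473)
    expect_equal(diff(axis)[1], 0.964, tolerance = 1e-3)
    path <- withr::local_tempfile(fileext = ".csv")
    ds0 <- SpectralDataset(matrix(runif(length(axis)), 1),
                           shift = axis, sampleIds = "S1")
    writeSpectraTable(ds0, path)
    expect_equal(nrow(readSpectraTable(path)), 3473L)
})

test_that("averageReplicates averages, preserves order, and is idempotent", {
    ds <- SpectralDataset(rbind(c(0, 2), c(2, 0), c(5, 5)),
                          shift = c(1, 2),
                          sampleIds = c("B", "B", "A"),
                          replicateIds = c("1", "2", "1"))
    av <- averageReplicates(ds)
    expect_identical(av$sample_id, c("B", "A"))   # first-appearance order
    expect_equal(unname(intensityMatrix(av)), rbind(c(1, 1), c(5, 5)))
    expect_equal(intensityMatrix(averageReplicates(av)),
                 intensityMatrix(av))
    # two identical scans reproduce the scan
    ds2 <- SpectralDataset(rbind(c(3, 7), c(3, 7)), shift = c(1, 2),
                           sampleIds = c("X", "X"),
                           replicateIds = c("1", "2"))
    expect_equal(as.numeric(intensityMatrix(averageReplicates(ds2))),
                 c(3, 7))
})

test_that("duplicate-scan study design collapses to one row per sample", {
    sim <- simulateDataset(smallSimConfig(nChannels = 60))
    expect_equal(ncol(sim$dataset), 166L)        # 83 samples x 2 scans
    av <- averageReplicates(sim$dataset)
    expect_equal(ncol(av), 83L)
    expect_identical(av$sample_id, unique(sim$dataset$sample_id))
})

test_that("cropRegion keeps a closed interval and composes idempotently", {
    axis <- seq(50, 3398, by = 2)
    ds <- SpectralDataset(matrix(seq_along(axis), 1), shift = axis,
                          sampleIds = "S1")
    cropped <- cropRegion(ds, 50, 1800)
    expect_equal(nrow(cropped), 876L)            # (1800 - 50)/2 + 1
    expect_equal(range(shiftAxis(cropped)), c(50, 1800))
    expect_identical(intensityMatrix(cropRegion(cropped, 50, 1800)),
                     intensityMatrix(cropped))
    # full-extent crop is the identity
    expect_identical(intensityMatrix(cropRegion(ds, 50, 3398)),
                     intensityMatrix(ds))
    expect_error(cropRegion(ds, 4000, 5000), "fewer than 2")
    expect_error(cropRegion(ds, 1800, 50))
})

test_that("dataset validity rejects bad axes and non-finite intensities", {
    expect_error(SpectralDataset(matrix(1:4, 2), shift = c(2, 1),
                                 sampleIds = c("A", "B")),
                 "strictly increasing")
    expect_error(SpectralDataset(matrix(c(1, NA, 3, 4), 2),
                                 shift = c(1, 2),
                                 sampleIds = c("A", "B")),
                 "finite")
})

test_that("referenceVector aligns by sample and errors on gaps", {
    ds <- makeTinyDataset(nSamples = 3, reps = 1)
    refs <- data.frame(sample_id = c("S02", "S01", "S03"),
                       element = "Ca", ppm = c(2, 1, 3))
    expect_equal(unname(referenceVector(ds, refs, "Ca")), c(1, 2, 3))
    expect_error(referenceVector(ds, refs, "Mg"), "not present")
    expect_error(referenceVector(ds, refs[-1, ], "Ca"), "missing")
})
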