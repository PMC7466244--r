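test_that("quasi-random split is sized, disjoint, seeded and range-safe", {
    set.seed(1)
    y <- rnorm(83)
    sp <- quasiRandomSplit(y, 42, seed = 7)
    expect_length(sp$cal, 42L)
    expect_length(sp$val, 41L)
    expect_length(intersect(sp$cal, sp$val), 0L)
    expect_identical(sort(c(sp$cal, sp$val)), 1:83)
    expect_identical(quasiRandomSplit(y, 42, seed = 7), sp)
    expect_false(identical(quasiRandomSplit(y, 42, seed = 8)$cal, sp$cal))
    # extremes are forced into calibration: validation never extrapolates
    for (s in 1:5) {
        sp2 <- quasiRandomSplit(y, 42, seed = s)
        expect_gte(min(y[sp2$val]), min(y[sp2$cal]))
        expect_lte(max(y[sp2$val]), max(y[sp2$cal]))
    }
    expect_error(quasiRandomSplit(y, 100))
    expect_error(quasiRandomSplit(y, 1))
})

test_that("a noiseless simulation calibrates essentially perfectly", {
    cfg <- smallSimConfig(seed = 5, nChannels = 400, noiseSd = 0,
                          multiplicativeSd = 0, baselineAmp = 0)
    sim <- simulateDataset(cfg)
    rep <- evaluatePipeline(sim$dataset, sim$references,
                            pipelineConfig(preprocessConfig("asls"),
                                           element = "Ca", AMax = 8))
    expect_equal(round(rep$R2C, 2), 1)
    sdY <- sd(sim$references$ppm[sim$references$element == "Ca"])
    expect_lt(rep$RMSECV, 1e-2 * sdY)
})

test_that("configured outlier exclusion reduces the calibration count", {
    sim <- simulateDataset(smallSimConfig(nChannels = 120))
    rep <- evaluatePipeline(sim$dataset, sim$references,
        pipelineConfig(preprocessConfig("boc"), element = "K", AMax = 3,
                       exclude = "S001"))
    expect_identical(rep$n_cal, 82L)
})

test_that("pipeline errors are annotated with their stage", {
    sim <- simulateDataset(smallSimConfig(nChannels = 120))
    expect_error(
        evaluatePipeline(sim$dataset, sim$references,
                         pipelineConfig(preprocessConfig("boc"),
                                        element = "Au", AMax = 3)),
        "reference alignment")
})

test_that("runGrid evaluates configs independently and marks best models", {
    sim <- simulateDataset(smallSimConfig(seed = 2, nChannels = 250))
    cfgs <- list(
        pipelineConfig(preprocessConfig("boc"), element = "Ca", AMax = 4),
        pipelineConfig(preprocessConfig("raw"), element = "Ca", AMax = 4),
        pipelineConfig(preprocessConfig("boc"), element = "Mg", AMax = 4),
        pipelineConfig(preprocessConfig("boc"), element = "Au", AMax = 4))
    grid <- runGrid(sim$dataset, sim$references, cfgs)
    expect_equal(nrow(grid), 4L)
    expect_true(is.na(grid$R2CV[4]))
    expect_match(grid$error[4], "reference alignment")
    # exactly one best per element with any finished row
    for (el in c("Ca", "Mg"))
        expect_equal(sum(grid$best[grid$element == el]), 1L)
    expect_false(grid$best[4])
    byEl <- grid[grid$element == "Ca" & !is.na(grid$RMSECV), ]
    expect_equal(byEl$RMSECV[byEl$best], min(byEl$RMSECV))
    expect_error(runGrid(sim$dataset, sim$references, list()), "empty")
})

test_that("reports are reproducible bit-identically", {
    sim <- simulateDataset(smallSimConfig(seed = 3, nChannels = 150))
    cfg <- list(pipelineConfig(preprocessConfig("boc"), element = "Zn",
                               AMax = 3, nCal = 42, splitSeed = 9))
    g1 <- runGrid(sim$dataset, sim$references, cfg)
    g2 <- runGrid(sim$dataset, sim$references, cfg)
    expect_identical(g1, g2)
    expect_identical(g1$n_cal, 42L)
    expect_identical(g1$n_val, 41L)
    expect_lte(g1$bias_cv^2, g1$RMSECV^2)
    expect_lte(g1$spectral_variables, 150L)
})

test_that("validation samples never influence calibration statistics", {
    sim <- simulateDataset(smallSimConfig(seed = 4, nChannels = 200))
    refs <- sim$references
    av <- averageReplicates(sim$dataset)
    y <- referenceVector(av, refs, "Fe")
    sp <- quasiRandomSplit(y, 42, seed = 1)
    cfg <- pipelineConfig(preprocessConfig("boc"), element = "Fe",
                          AMax = 4, splitIndices = sp)
    r1 <- evaluatePipeline(sim$dataset, refs, cfg)
    refs2 <- refs
    pert <- refs2$element == "Fe" &
        refs2$sample_id %in% av$sample_id[sp$val]
    refs2$ppm[pert] <- refs2$ppm[pert] + 1000
    r2 <- evaluatePipeline(sim$dataset, refs2, cfg)
    same <- c("R2C", "RMSEC", "R2CV", "RMSECV", "bias_cv",
              "spectral_variables", "A")
    expect_identical(r1[same], r2[same])
    expect_false(identical(r1$RMSEP, r2$RMSEP))
})

test_that("report tables are written as CSV and aligned text", {
    sim <- simulateDataset(smallSimConfig(seed = 6, nChannels = 100))
    grid <- runGrid(sim$dataset, sim$references,
                    list(pipelineConfig(preprocessConfig("boc"),
                                        element = "Na", AMax = 3)))
    stem <- withr::local_tempfile()
    paths <- writeReportTable(grid, stem)
    expect_true(all(file.exists(paths)))
    back <- read.csv(paths[1])
    expect_equal(back$RMSECV, grid$RMSECV)
    expect_match(readLines(paths[2])[1], "element")
})
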