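test_that("the component library carries the expected band structure", {
    shift <- seq(50, 3398, length.out = 1200)
    lib <- buildComponentLibrary(shift, seed = 1)
    peaks <- attr(lib, "peaks")
    expect_true(1003 %in% peaks$protein$center)  # phenylalanine ring breathing
    expect_true(all(c("lactose", "protein", "lipid", "water") %in% names(lib)))
    # every mineral component has support in the chelated-backbone window
    minerals <- grep("^mineral_", names(lib), value = TRUE)
    expect_length(minerals, 7L)
    low <- shift >= 170 & shift <= 220
    for (mn in minerals) {
        expect_gt(max(lib[[mn]][low]), 0.05)
        expect_true(all(lib[[mn]] >= 0))
        centers <- peaks[[mn]]$center
        expect_true(all(centers >= 170 & centers <= 1665))
    }
    for (nm in names(lib)) expect_true(all(lib[[nm]] >= 0))
})

test_that("the same seed reproduces the dataset bit for bit", {
    a <- simulateDataset(smallSimConfig(seed = 42, nChannels = 80))
    b <- simulateDataset(smallSimConfig(seed = 42, nChannels = 80))
    expect_identical(intensityMatrix(a$dataset), intensityMatrix(b$dataset))
    expect_identical(a$references, b$references)
    c <- simulateDataset(smallSimConfig(seed = 43, nChannels = 80))
    expect_false(identical(intensityMatrix(a$dataset),
                           intensityMatrix(c$dataset)))
})

test_that("the study layout yields 83 samples from 19 formulas, scanned twice", {
    sim <- simulateDataset(smallSimConfig(nChannels = 60))
    ds <- sim$dataset
    expect_equal(ncol(ds), 166L)
    expect_equal(length(unique(ds$sample_id)), 83L)
    expect_equal(length(unique(ds$formula_id)), 19L)
    expect_setequal(unique(ds$powder_pct), c(3, 5, 8, 10, 13))
    expect_setequal(unique(sim$references$element),
                    c("Ca", "Mg", "K", "Na", "Cu", "Fe", "Zn"))
})

test_that("element concentration is exactly proportional to powder level", {
    sim <- simulateDataset(smallSimConfig(nChannels = 60))
    refs <- sim$references
    meta <- unique(data.frame(sample_id = sim$dataset$sample_id,
                              formula = sim$dataset$formula_id,
                              level = sim$dataset$powder_pct))
    merged <- merge(refs, meta, by = "sample_id")
    for (el in c("Ca", "Cu")) {
        sub <- merged[merged$element == el, ]
        dens <- sub$ppm / sub$level
        perFormula <- tapply(dens, sub$formula, function(v) diff(range(v)))
        expect_lt(max(perFormula), 1e-12)
    }
})

test_that("simulated concentration ranges track the study's reference table", {
    sim <- simulateDataset(simulationConfig(nChannels = 120, seed = 1))
    rng <- range(sim$references$ppm[sim$references$element == "Ca"])
    expect_gt(rng[1], 3.002 * 0.9);  expect_lt(rng[1], 3.002 * 1.1)
    expect_gt(rng[2], 25.295 * 0.9); expect_lt(rng[2], 25.295 * 1.1)
})

test_that("with noise, baseline and scan jitter off, data equal C S exactly", {
    cfg <- smallSimConfig(nChannels = 90, noiseSd = 0, baselineAmp = 0,
                          multiplicativeSd = 0)
    sim <- simulateDataset(cfg)
    av <- averageReplicates(sim$dataset)
    expect_equal(unname(intensityMatrix(av)),
                 unname(sim$truth$C %*% sim$truth$S), tolerance = 1e-12)
    # replicate scans are then identical
    m <- intensityMatrix(sim$dataset)
    expect_identical(m[1, ], m[2, ])
})

test_that("noise grows above 1800 cm^-1", {
    cfg <- smallSimConfig(nChannels = 800, baselineAmp = 0,
                          multiplicativeSd = 0, noiseSd = 2)
    sim <- simulateDataset(cfg)
    m <- intensityMatrix(sim$dataset)
    resid <- m - sim$truth$clean[rep(seq_len(83),
                                     each = cfg$replicateCount), ]
    shift <- shiftAxis(sim$dataset)
    sdLow <- sd(resid[, shift < 1500])
    sdHigh <- sd(resid[, shift > 3100])
    expect_gt(sdHigh / sdLow, 2)
})

test_that("salt spectra differ most in the low-frequency window", {
    ds <- simulateSaltSpectra(seed = 2)
    expect_equal(ncol(ds), 8L)
    m <- intensityMatrix(ds)
    shift <- shiftAxis(ds)
    lowBand <- shift >= 50 & shift <= 465
    midBand <- shift > 465 & shift <= 1800
    pairDiff <- function(band) {
        d <- 0
        for (i in 1:7) for (j in (i + 1):8)
            d <- max(d, mean(abs(m[i, band] - m[j, band])))
        d
    }
    expect_gt(pairDiff(lowBand), pairDiff(midBand))
    expect_error(simulateSaltSpectra(c("NaCl", "KBr")), "unknown salt")
    # water control carries no salt peaks: it sits at or below every
    # salt spectrum in the low band (up to noise)
    withW <- simulateSaltSpectra(c("water", "NaCl"), seed = 3)
    mw <- intensityMatrix(withW)
    expect_gt(mean(mw[2, lowBand] - mw[1, lowBand]), 5)
})
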