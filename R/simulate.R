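## Synthetic aqueous infant-formula Raman data with known ground truth.
##
## The generator follows a bilinear model: each scan is
##   intensity = (matrix constituents + mineral-linked modulation) +
##               fluorescence baseline, all times a per-scan
##               multiplicative factor, plus heteroscedastic shot noise
## with the mineral modulation exactly proportional to the element's
## concentration, so parameter-recovery tests have an unambiguous truth.

peakProfile <- function(shift, center, fwhm, amplitude,
                        shape = c("gaussian", "lorentzian")) {
    shape <- match.arg(shape)
    stopifnot(fwhm > 0, amplitude >= 0)
    if (shape == "gaussian")
        amplitude * exp(-4 * log(2) * (shift - center)^2 / fwhm^2)
    else
        amplitude / (1 + (2 * (shift - center) / fwhm)^2)
}

profileFromPeaks <- function(shift, peaks) {
    out <- numeric(length(shift))
    for (i in seq_len(nrow(peaks)))
        out <- out + peakProfile(shift, peaks$center[i], peaks$fwhm[i],
                                 peaks$amplitude[i], peaks$shape[i])
    out
}

elementSymbols <- c("Ca", "Mg", "K", "Na", "Cu", "Fe", "Zn")

## Table-1-style per-element profile: ppm per % w/w powder, so that
## sample concentration = density x powder level spans the observed
## ranges over levels 3-13% w/w. modulation presets encode how strongly
## the element's binding perturbs the matrix bands ("strong" = Ca-like,
## "weak" = Cu-like).
defaultElementProfile <- function() {
    data.frame(
        element  = elementSymbols,
        densityLo = c(3.002 / 3, 0.281 / 3, 0.129 / 3, 0.144 / 3,
                      0.009 / 3, 0.016 / 3, 0.045 / 3),
        densityHi = c(25.295 / 13, 2.537 / 13, 17.319 / 13, 9.133 / 13,
                      0.563 / 13, 3.13 / 13, 2.575 / 13),
        modulation = c("strong", "strong", "moderate", "moderate",
                       "weak", "strong", "strong"),
        stringsAsFactors = FALSE)
}

#' Component spectra of the aqueous infant-formula matrix
#'
#' Builds the spectral library of the bilinear simulator: lactose
#' (glycosidic-bond bands near 355, 445, 850, 877, 950 and 1070 cm^-1),
#' protein (phenylalanine ring breathing at 1003, amide II at 1555,
#' amide I at 1660, N-H at 3060), lipid (CH2/CH3 modes at 1262, 1303,
#' 1442, 1746, 2855, 2927, 3005), water (a broad O-H stretch envelope at
#' 3200-3400 and a low-frequency band near 170 cm^-1), and one
#' modulation component per mineral element with support concentrated in
#' 170-220 cm^-1 (chelated backbones) and 760-1665 cm^-1 (amino-acid
#' binding region). Mineral band positions and amplitudes are drawn from
#' the seeded generator so each element's footprint is distinct; all
#' component intensities are non-negative.
#'
#' @param shift Raman-shift axis (cm^-1)
#' @param seed integer seed for the mineral components
#' @return named list of component intensity vectors plus an attribute
#'   \code{"peaks"} holding each component's peak table
#' @export
buildComponentLibrary <- function(shift, seed = 1L) {
    g <- function(center, fwhm, amplitude, shape = "gaussian")
        data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
                   shape = shape, stringsAsFactors = FALSE)
    peaks <- list(
        lactose = rbind(
            g(355, 28, 0.55), g(445, 22, 0.50), g(850, 16, 0.65),
            g(877, 16, 0.60), g(950, 18, 0.45), g(1070, 26, 0.80),
            g(1121, 18, 0.35)),
        protein = rbind(
            g(1003, 9, 1.00), g(1262, 24, 0.25), g(1555, 30, 0.35),
            g(1660, 34, 0.80), g(3060, 40, 0.30)),
        lipid = rbind(
            g(1262, 22, 0.30), g(1303, 20, 0.45), g(1442, 26, 0.90),
            g(1746, 20, 0.35), g(2855, 34, 0.85), g(2927, 38, 1.00),
            g(3005, 30, 0.40)),
        water = rbind(
            g(170, 120, 0.50), g(3250, 220, 0.85, "lorentzian"),
            g(3400, 150, 0.65)))
    set.seed(seed)
    for (el in elementSymbols) {
        lowC <- stats::runif(1, 170, 220)
        midC <- sort(stats::runif(3, 760, 1665))
        amps <- stats::runif(4, 0.3, 1.0)
        peaks[[paste0("mineral_", el)]] <- rbind(
            g(lowC, 30, amps[1L]),
            g(midC[1L], 18, amps[2L]),
            g(midC[2L], 18, amps[3L]),
            g(midC[3L], 18, amps[4L]))
    }
    lib <- lapply(peaks, function(p) profileFromPeaks(shift, p))
    attr(lib, "peaks") <- peaks
    lib
}

#' Simulation configuration for the aqueous-formula study design
#'
#' Defaults emulate the study layout: 19 powder formulas reconstituted
#' at 3, 5, 8, 10 and 13% w/w into 83 aqueous samples (15 formulas at
#' all five levels, a further 7 scans of mostly-commercial formulas at
#' 13%, one sample at 8%), duplicate scans per sample, an axis of 3473
#' channels over 50-3398 cm^-1, element concentration ranges matching
#' the ICP-AES reference table, an exponential-decay fluorescence
#' baseline with a linear tilt, and additive noise whose standard
#' deviation grows smoothly above 1800 cm^-1.
#'
#' @param nFormulas number of powder formulas (default 19)
#' @param levels powder concentrations, % w/w
#' @param elementProfile data.frame with \code{element},
#'   \code{densityLo}, \code{densityHi} (ppm per % w/w) and
#'   \code{modulation} preset (\code{"strong"}, \code{"moderate"},
#'   \code{"weak"})
#' @param axisLo,axisHi,nChannels the shift axis (cm^-1)
#' @param baselineAmp mean fluorescence amplitude (cps)
#' @param baselineDecay exponential decay constant (cm^-1)
#' @param noiseSd additive noise sd below 1800 cm^-1 (cps)
#' @param noiseInflation factor by which the sd has grown at the
#'   high-shift end of the axis
#' @param multiplicativeSd sd of the per-scan log-normal intensity factor
#' @param replicateCount scans per sample (default 2)
#' @param modulationScale cps of mineral-linked signal per unit of
#'   normalized concentration at the "strong" preset
#' @param seed integer seed
#' @return a list of class \code{"SimulationConfig"}
#' @export
simulationConfig <- function(nFormulas = 19L,
                             levels = c(3, 5, 8, 10, 13),
                             elementProfile = defaultElementProfile(),
                             axisLo = 50, axisHi = 3398,
                             nChannels = 3473L,
                             baselineAmp = 900, baselineDecay = 1500,
                             noiseSd = 1.5, noiseInflation = 4,
                             multiplicativeSd = 0.03,
                             replicateCount = 2L,
                             modulationScale = 35,
                             seed = 1L) {
    stopifnot(nFormulas >= 1L, all(levels > 0), all(levels < 100),
              nChannels >= 2L, axisLo < axisHi, baselineAmp >= 0,
              baselineDecay > 0, noiseSd >= 0, noiseInflation >= 1,
              multiplicativeSd >= 0, replicateCount >= 1L,
              modulationScale >= 0)
    structure(list(nFormulas = as.integer(nFormulas), levels = levels,
                   elementProfile = elementProfile, axisLo = axisLo,
                   axisHi = axisHi, nChannels = as.integer(nChannels),
                   baselineAmp = baselineAmp,
                   baselineDecay = baselineDecay, noiseSd = noiseSd,
                   noiseInflation = noiseInflation,
                   multiplicativeSd = multiplicativeSd,
                   replicateCount = as.integer(replicateCount),
                   modulationScale = modulationScale,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

## noise sd profile: flat below 1800 cm^-1, growing linearly to
## noiseInflation x at the axis end (the gradual high-shift inflation
## seen in fiber-probe CCD spectra)
noiseSdProfile <- function(shift, config) {
    ramp <- pmin(1, pmax(0, (shift - 1800) /
                             max(config$axisHi - 1800, 1)))
    config$noiseSd * (1 + (config$noiseInflation - 1) * ramp)
}

## The 83-sample layout: formulas F01..F14 are "produced", C01..C05
## "commercial". F01..F14 + C01 get all five levels; C01..C05, F01, F02
## get an extra 13% sample; F03 gets an extra 8% sample.
studyLayout <- function(config) {
    lv <- config$levels
    full <- expand.grid(formula = c(sprintf("F%02d", 1:14), "C01"),
                        level = lv, stringsAsFactors = FALSE)
    full <- full[order(full$formula, full$level), ]
    extra13 <- data.frame(formula = c(sprintf("C%02d", 1:5), "F01", "F02"),
                          level = max(lv), stringsAsFactors = FALSE)
    extra8 <- data.frame(formula = "F03", level = lv[3L],
                         stringsAsFactors = FALSE)
    layout <- rbind(full, extra13, extra8)
    layout$sample_id <- sprintf("S%03d", seq_len(nrow(layout)))
    rownames(layout) <- NULL
    layout
}

#' Simulate an aqueous infant-formula Raman study
#'
#' Draws per-formula mineral densities (ppm per % w/w) from the
#' configured ranges, so every element's concentration is exactly
#' proportional to the powder level within a formula; builds each scan
#' as matrix-constituent components scaled with the powder level, plus
#' mineral-linked modulation proportional to the element's ppm, plus a
#' per-sample fluorescence baseline (amplitude x exp(-shift/decay) plus
#' a linear tilt), all scaled by a per-scan multiplicative factor, plus
#' heteroscedastic additive noise. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a [simulationConfig()]
#' @return list with \code{dataset} (a per-scan
#'   \linkS4class{SpectralDataset}), \code{references} (long
#'   \code{data.frame}: \code{sample_id}, \code{element}, \code{ppm}),
#'   and \code{truth} (class \code{"GroundTruth"}: concentration matrix
#'   \code{C}, component matrix \code{S}, per-scan baselines, scan
#'   factors, the noiseless scan matrix, and the seed)
#' @export
simulateDataset <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    shift <- seq(config$axisLo, config$axisHi,
                 length.out = config$nChannels)
    lib <- buildComponentLibrary(shift, seed = config$seed)
    layout <- studyLayout(config)
    if (config$nFormulas != length(unique(layout$formula)))
        layout <- layout[layout$formula %in%
                         unique(layout$formula)[seq_len(config$nFormulas)], ]
    n <- nrow(layout)
    prof <- config$elementProfile
    nEl <- nrow(prof)
    forms <- unique(layout$formula)
    ## per-formula densities, ppm per % w/w: stratified over the design
    ## range (one draw per equal-width stratum, randomly assigned to
    ## formulas) so every element spans its formulation range
    nF <- length(forms)
    dens <- vapply(seq_len(nEl), function(e) {
        u <- (sample(nF) - stats::runif(nF)) / nF
        prof$densityLo[e] + u * (prof$densityHi[e] - prof$densityLo[e])
    }, numeric(nF))
    dimnames(dens) <- list(forms, prof$element)
    ppm <- dens[layout$formula, , drop = FALSE] * layout$level
    rownames(ppm) <- layout$sample_id

    modFactor <- c(strong = 1, moderate = 0.45, weak = 0.08)
    matrixNames <- c("lactose", "protein", "lipid", "water")
    matrixBase <- c(lactose = 30, protein = 14, lipid = 12, water = 350)
    ## concentration matrix C (samples x components): matrix weights
    ## scale with powder level (water stays near-constant), mineral
    ## weights are the normalized ppm times the modulation preset
    C <- matrix(0, n, length(matrixNames) + nEl,
                dimnames = list(layout$sample_id,
                                c(matrixNames,
                                  paste0("mineral_", prof$element))))
    for (k in matrixNames)
        C[, k] <- if (k == "water") matrixBase[k] * (1 - layout$level / 100)
                  else matrixBase[k] * layout$level / 10
    midDens <- (prof$densityLo + prof$densityHi) / 2
    meanPpm <- midDens * mean(config$levels)
    for (e in seq_len(nEl))
        C[, length(matrixNames) + e] <-
            config$modulationScale *
            modFactor[[prof$modulation[e]]] *
            ppm[, e] / meanPpm[e]
    S <- do.call(rbind, lib[colnames(C)])
    clean <- C %*% S                       # samples x channels

    nScan <- n * config$replicateCount
    scanOf <- rep(seq_len(n), each = config$replicateCount)
    baseAmp <- config$baselineAmp *
        stats::rlnorm(nScan, meanlog = 0, sdlog = 0.4)
    ## linear tilt scales with the fluorescence amplitude, so a
    ## zero-baseline configuration is exactly bilinear
    tilt <- stats::runif(nScan, -0.02, 0.05) * config$baselineAmp / 900
    scanFactor <- stats::rlnorm(nScan, 0, config$multiplicativeSd)
    sdProf <- noiseSdProfile(shift, config)
    intens <- matrix(0, nScan, config$nChannels)
    baselines <- matrix(0, nScan, config$nChannels)
    for (i in seq_len(nScan)) {
        bl <- baseAmp[i] * exp(-shift / config$baselineDecay) +
            tilt[i] * (shift - config$axisLo)
        baselines[i, ] <- bl
        noise <- stats::rnorm(config$nChannels, sd = sdProf)
        intens[i, ] <- scanFactor[i] * (clean[scanOf[i], ] + bl) + noise
    }
    dataset <- SpectralDataset(
        intens, shift = shift,
        sampleIds = layout$sample_id[scanOf],
        replicateIds = as.character(rep(seq_len(config$replicateCount), n)),
        meta = data.frame(formula_id = layout$formula[scanOf],
                          powder_pct = layout$level[scanOf]))
    references <- data.frame(
        sample_id = rep(layout$sample_id, nEl),
        element = rep(prof$element, each = n),
        ppm = as.vector(ppm),
        stringsAsFactors = FALSE)
    truth <- structure(list(C = C, S = S, ppm = ppm,
                            densities = dens, layout = layout,
                            baselines = baselines,
                            scanFactor = scanFactor,
                            clean = clean, shift = shift,
                            seed = config$seed),
                       class = "GroundTruth")
    list(dataset = dataset, references = references, truth = truth)
}

#' Simulate chloride-salt control spectra
#'
#' One spectrum per salt: the water background plus salt-specific
#' low-frequency features confined to 50-465 cm^-1 (where the chloride
#' solutions differ most) and additive noise inflating above
#' 1800 cm^-1. The pseudo-salt \code{"water"} gives the background-only
#' control.
#'
#' @param salts character vector from \code{CaCl2, MgCl2, KCl, NaCl,
#'   MnCl2, FeCl3, CuCl2, ZnCl2} (plus \code{"water"})
#' @param seed integer seed
#' @param config a [simulationConfig()] (axis and noise settings reused)
#' @return a \linkS4class{SpectralDataset}, one column per salt
#' @export
simulateSaltSpectra <- function(salts = c("CaCl2", "MgCl2", "KCl", "NaCl",
                                          "MnCl2", "FeCl3", "CuCl2",
                                          "ZnCl2"),
                                seed = 1L,
                                config = simulationConfig(seed = seed)) {
    known <- c("CaCl2", "MgCl2", "KCl", "NaCl", "MnCl2", "FeCl3",
               "CuCl2", "ZnCl2", "water")
    bad <- setdiff(salts, known)
    if (length(bad)) stop("unknown salt(s): ", paste(bad, collapse = ", "))
    set.seed(seed)
    shift <- seq(config$axisLo, config$axisHi,
                 length.out = config$nChannels)
    water <- profileFromPeaks(shift, rbind(
        data.frame(center = 170, fwhm = 120, amplitude = 60,
                   shape = "gaussian"),
        data.frame(center = 3250, fwhm = 220, amplitude = 110,
                   shape = "lorentzian"),
        data.frame(center = 3400, fwhm = 150, amplitude = 80,
                   shape = "gaussian")))
    sdProf <- noiseSdProfile(shift, config)
    centers <- stats::setNames(seq(80, 340, length.out = 8L),
                               setdiff(known, "water"))
    spectra <- vapply(salts, function(s) {
        y <- water
        if (s != "water") {
            cs <- centers[[s]]
            y <- y + peakProfile(shift, cs, 30, 90) +
                peakProfile(shift, cs + 70, 22, 45) +
                peakProfile(shift, 210, 60, 25)   # shared hydration band
        }
        y + stats::rnorm(length(shift), sd = sdProf)
    }, numeric(length(shift)))
    SpectralDataset(t(spectra), shift = shift, sampleIds = salts)
}
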