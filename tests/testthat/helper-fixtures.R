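# Small seeded fixtures shared across test files.

# tiny simulated calibration problem: y depends linearly on a few
# channels of a smooth spectral-like X
makeLinearSpectra <- function(n = 30, J = 80, informative = 10:20,
                              noise = 0, seed = 1) {
    set.seed(seed)
    shift <- seq_len(J)
    X <- t(vapply(seq_len(n), function(i) {
        h <- runif(5, 0.5, 2)
        cen <- c(15, 30, 45, 60, 70)
        rowSums(vapply(1:5, function(k)
            h[k] * exp(-(shift - cen[k])^2 / 18), numeric(J)))
    }, numeric(J)))
    beta <- numeric(J)
    beta[informative] <- seq_along(informative) / length(informative)
    y <- as.numeric(X %*% beta) + rnorm(n, sd = noise)
    list(X = X, y = y, beta = beta)
}

# a small per-scan dataset with duplicate scans for io tests
makeTinyDataset <- function(nSamples = 4, J = 12, reps = 2, seed = 3) {
    set.seed(seed)
    ids <- rep(sprintf("S%02d", seq_len(nSamples)), each = reps)
    SpectralDataset(matrix(runif(nSamples * reps * J, 0, 100),
                           nrow = nSamples * reps),
                    shift = seq(50, 50 + 2 * (J - 1), by = 2),
                    sampleIds = ids,
                    replicateIds = as.character(rep(seq_len(reps),
                                                    nSamples)))
}

# small default simulation reused by selection/experiment tests
smallSimConfig <- function(seed = 11, nChannels = 500, ...) {
    simulationConfig(nChannels = nChannels, seed = seed, ...)
}
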