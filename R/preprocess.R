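#' Preprocessing configuration
#'
#' Bundles the tunables of the four spectral pre-treatments. Defaults are
#' the standard literature settings for penalized-least-squares baseline
#' estimation on Raman data: \code{lambda = 1e5} (smoothness penalty,
#' dimensionless), \code{p = 0.01} (AsLS asymmetry weight), and a
#' window-7 / order-2 Savitzky-Golay first derivative.
#'
#' @param method one of \code{"asls"}, \code{"airpls"}, \code{"boc"},
#'   \code{"sg1"}, \code{"raw"}
#' @param lambda smoothness penalty, > 0
#' @param p AsLS asymmetry weight, in (0, 1): points above the running
#'   baseline get weight \code{p}, points below get \code{1 - p}
#' @param maxIter iteration cap for the reweighting loops
#' @param tol airPLS termination: stop when the l1 norm of negative
#'   residuals falls below \code{tol} times the l1 norm of the input
#' @param window Savitzky-Golay window (odd, > \code{polyorder})
#' @param polyorder Savitzky-Golay polynomial degree (>= 1)
#' @param diffOrder order of the Whittaker difference penalty (default 2)
#' @return a list of class \code{"PreprocessConfig"}
#' @export
preprocessConfig <- function(method = c("asls", "airpls", "boc", "sg1", "raw"),
                             lambda = 1e5, p = 0.01, maxIter = 50L,
                             tol = 1e-3, window = 7L, polyorder = 2L,
                             diffOrder = 2L) {
    method <- match.arg(method)
    stopifnot(lambda > 0, p > 0, p < 1, maxIter >= 1, tol > 0,
              window %% 2L == 1L, window >= 3L, polyorder >= 1L,
              window > polyorder, diffOrder >= 1L)
    if (method == "airpls") maxIter <- min(maxIter, 30L)
    structure(list(method = method, lambda = lambda, p = p,
                   maxIter = as.integer(maxIter), tol = tol,
                   window = as.integer(window),
                   polyorder = as.integer(polyorder),
                   diffOrder = as.integer(diffOrder)),
              class = "PreprocessConfig")
}

#' Whittaker smoother with pointwise weights
#'
#' Solves the penalized least-squares problem
#' \deqn{\min_z \sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^d z)_i^2}
#' via the sparse banded normal equations
#' \eqn{(W + \lambda D'D) z = W y}, with \eqn{D} the order-\eqn{d}
#' difference operator. With the default second-order penalty the null
#' space of the penalty is the affine functions, so \code{z} tends to the
#' ordinary least-squares line as \eqn{\lambda \to \infty}.
#'
#' @param y numeric vector (length >= 3)
#' @param w non-negative weights, same length as \code{y}, not all zero
#' @param lambda penalty, >= 0 (\code{0} returns \code{y})
#' @param diffOrder difference order of the penalty (default 2)
#' @return the smoothed vector
#' @export
whittakerSmooth <- function(y, w = rep(1, length(y)), lambda,
                            diffOrder = 2L) {
    n <- length(y)
    stopifnot(n >= 3L, length(w) == n, all(w >= 0), lambda >= 0)
    if (all(w == 0)) stop("weights are all zero: system is singular")
    if (lambda == 0) return(y)
    D <- Matrix::diff(Matrix::Diagonal(n), differences = diffOrder)
    A <- Matrix::Diagonal(n, x = w) + lambda * Matrix::crossprod(D)
    as.numeric(Matrix::solve(A, w * y))
}

#' Baseline-correct one spectrum
#'
#' Three baseline models share the interface:
#' \describe{
#'   \item{asls}{asymmetric least squares: iterate
#'     \code{z = whittakerSmooth(y, w, lambda)} with
#'     \code{w_i = p} where \code{y_i > z_i} and \code{1 - p} elsewhere,
#'     from \code{w = 1}, until the weights stop changing or
#'     \code{maxIter} is reached.}
#'   \item{airpls}{adaptive iteratively reweighted penalized least
#'     squares: at iteration \code{t}, residuals \code{d = y - z} at or
#'     above the baseline get weight 0 and negative residuals get weight
#'     \code{exp(t |d_i| / |d^-|)} with \code{|d^-|} the l1 norm of the
#'     negative residuals; terminate when \code{|d^-| < tol * |y|_1}.}
#'   \item{boc}{baseline offset correction: a constant baseline equal to
#'     \code{min(y)}.}
#' }
#' In every case \code{corrected = y - baseline}, so baseline plus
#' corrected reconstructs the input.
#'
#' @param y numeric intensity vector (finite)
#' @param config a [preprocessConfig()] with method \code{asls},
#'   \code{airpls} or \code{boc}
#' @return a list of class \code{"BaselineResult"} with elements
#'   \code{baseline}, \code{corrected}, \code{weights}, \code{nIter},
#'   \code{converged}, \code{method}
#' @export
baselineCorrect <- function(y, config = preprocessConfig("asls")) {
    if (anyNA(y) || any(!is.finite(y))) stop("input must be finite")
    m <- config$method
    if (!m %in% c("asls", "airpls", "boc"))
        stop("baselineCorrect requires method asls, airpls or boc")
    n <- length(y)
    if (m == "boc") {
        z <- rep(min(y), n)
        return(structure(list(baseline = z, corrected = y - z,
                              weights = rep(1, n), nIter = 1L,
                              converged = TRUE, method = m),
                         class = "BaselineResult"))
    }
    w <- rep(1, n)
    z <- y
    converged <- FALSE
    it <- 0L
    if (m == "asls") {
        for (it in seq_len(config$maxIter)) {
            z <- whittakerSmooth(y, w, config$lambda, config$diffOrder)
            wNew <- ifelse(y > z, config$p, 1 - config$p)
            if (max(abs(wNew - w)) == 0) { converged <- TRUE; break }
            w <- wNew
        }
    } else {                               # airpls
        normY <- sum(abs(y))
        for (it in seq_len(config$maxIter)) {
            z <- whittakerSmooth(y, w, config$lambda, config$diffOrder)
            d <- y - z
            neg <- d < 0
            dssn <- sum(abs(d[neg]))
            w <- numeric(n)                # >= baseline -> 0
            if (any(neg)) w[neg] <- exp(it * abs(d[neg]) / dssn)
            if (dssn < config$tol * normY) { converged <- TRUE; break }
        }
    }
    structure(list(baseline = z, corrected = y - z, weights = w,
                   nIter = it, converged = converged, method = m),
              class = "BaselineResult")
}

#' @export
print.BaselineResult <- function(x, ...) {
    cat(sprintf("BaselineResult (%s): %d channels, %d iteration(s), %s\n",
                x$method, length(x$baseline), x$nIter,
                if (x$converged) "converged" else "NOT converged"))
    invisible(x)
}

#' Savitzky-Golay first derivative
#'
#' First derivative by local polynomial fitting (default: 7 smoothing
#' points, 2nd-degree polynomial), in units of intensity per channel
#' index. Edges are handled by evaluating the polynomial fit of the
#' terminal window at the edge positions, so the operator is exactly
#' linear and reproduces the analytic derivative of any polynomial up to
#' \code{polyorder} at interior points.
#'
#' @param y numeric vector, length >= \code{window}
#' @param window odd window width (default 7)
#' @param polyorder polynomial degree (default 2)
#' @return the derivative vector, same length as \code{y}
#' @export
sgDerivative <- function(y, window = 7L, polyorder = 2L) {
    stopifnot(window %% 2L == 1L, window > polyorder,
              length(y) >= window)
    as.numeric(signal::sgolayfilt(y, p = polyorder, n = window, m = 1L))
}

#' Apply a pre-treatment to every spectrum of a dataset
#'
#' Dispatches on \code{config$method}: the three baseline corrections are
#' applied per spectrum (column); \code{"sg1"} applies the
#' Savitzky-Golay first derivative (requiring a uniform axis, checked to
#' 1e-6 relative spacing); \code{"raw"} returns the dataset unchanged.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param config a [preprocessConfig()]
#' @return a \code{SpectralDataset} of pre-treated intensities
#' @export
preprocessDataset <- function(dataset, config) {
    stopifnot(methods::is(dataset, "SpectralDataset"),
              inherits(config, "PreprocessConfig"))
    if (config$method == "raw") return(dataset)
    a <- SummarizedExperiment::assay(dataset, "intensity")
    if (config$method == "sg1") {
        d <- diff(shiftAxis(dataset))
        if (diff(range(d)) > 1e-6 * mean(d))
            stop("Savitzky-Golay derivative requires a uniform axis ",
                 "(relative spacing deviation > 1e-6)")
        out <- apply(a, 2L, sgDerivative,
                     window = config$window, polyorder = config$polyorder)
    } else {
        out <- apply(a, 2L, function(col)
            baselineCorrect(col, config)$corrected)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = out),
        rowData = SummarizedExperiment::rowData(dataset),
        colData = SummarizedExperiment::colData(dataset))
    methods::new("SpectralDataset", se)
}
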