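#' CalibrationCurve: an accepted ICP-AES standard curve
#'
#' Ordinary least-squares line of instrument response on standard
#' concentration, fit on a blank plus multi-element standards and kept
#' only if it passes both instrument-qualification gates: correlation
#' coefficient > 0.995 and back-prediction of every non-blank standard
#' within 10% of its nominal value.
#'
#' @slot element element symbol (may be "")
#' @slot wavelength monitoring wavelength, nm (NA if unspecified)
#' @slot standards standard concentrations, ppm (including the blank)
#' @slot responses instrument signals
#' @slot slope,intercept the fitted line
#' @slot r2 squared correlation coefficient
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
         representation(element = "character", wavelength = "numeric",
                        standards = "numeric", responses = "numeric",
                        slope = "numeric", intercept = "numeric",
                        r2 = "numeric"))

#' @export
setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf("CalibrationCurve%s: %d standards (%g-%g ppm), r2 = %.5f\n",
                if (nzchar(object@element))
                    paste0(" [", object@element, "]") else "",
                length(object@standards), min(object@standards),
                max(object@standards), object@r2))
})

#' Fit an ICP-AES calibration curve with quality gates
#'
#' @param standards standard concentrations (ppm), non-negative,
#'   at least 3 points including a blank (0)
#' @param responses instrument signals, same length
#' @param element optional element symbol
#' @param wavelength optional monitoring wavelength (nm)
#' @return a \linkS4class{CalibrationCurve}; rejection (correlation
#'   coefficient <= 0.995 or any non-blank standard back-predicted more
#'   than 10% off nominal) is an error naming the violated gate
#' @examples
#' fitCalibrationCurve(c(0, 12.5, 25, 50), c(0.1, 12.6, 25.1, 50.1))
#' @export
fitCalibrationCurve <- function(standards, responses, element = "",
                                wavelength = NA_real_) {
    stopifnot(length(standards) == length(responses))
    if (length(standards) < 3L)
        stop("at least 3 calibration points are required")
    if (any(standards < 0))
        stop("standard concentrations must be non-negative")
    if (!any(standards == 0))
        stop("a blank (0 ppm) standard is required")
    fit <- stats::lm(responses ~ standards)
    slope <- stats::coef(fit)[["standards"]]
    intercept <- stats::coef(fit)[["(Intercept)"]]
    r <- stats::cor(standards, responses)
    if (!is.finite(r) || r <= 0.995)
        stop(sprintf("curve rejected: correlation coefficient %.5f <= 0.995", r))
    if (slope == 0) stop("curve rejected: zero slope")
    nb <- standards > 0
    back <- (responses[nb] - intercept) / slope
    relErr <- abs(back - standards[nb]) / standards[nb]
    if (max(relErr) > 0.10)
        stop(sprintf(paste0("curve rejected: maximum back-prediction error ",
                            "%.1f%% > 10%% (standard %g ppm)"),
                     100 * max(relErr), standards[nb][which.max(relErr)]))
    methods::new("CalibrationCurve", element = element,
                 wavelength = wavelength, standards = standards,
                 responses = responses, slope = slope,
                 intercept = intercept, r2 = r^2)
}

#' Expected instrument response at a concentration
#'
#' @param curve a \linkS4class{CalibrationCurve}
#' @param concentration ppm
#' @return predicted signal
#' @export
predictResponse <- function(curve, concentration) {
    curve@intercept + curve@slope * concentration
}

#' Quantify a sample from its instrument response
#'
#' \code{ppm = dilutionFactor * (response - intercept) / slope}. The
#' dilution factor restores the concentration of the undiluted digest
#' (e.g. 10 for a 1:10 v/v dilution).
#'
#' @param curve an accepted \linkS4class{CalibrationCurve}
#' @param response instrument signal(s)
#' @param dilutionFactor >= 1 (default 1)
#' @return concentration(s), ppm
#' @export
quantifySample <- function(curve, response, dilutionFactor = 1) {
    stopifnot(dilutionFactor >= 1)
    if (curve@slope == 0) stop("zero slope: cannot quantify")
    dilutionFactor * (response - curve@intercept) / curve@slope
}

#' Summarize replicate measurements per element
#'
#' Reduces a table of replicate measurements (columns \code{sample_id},
#' \code{element}, \code{ppm}) to one summary row per element: min, max,
#' mean and median of the per-sample replicate means, and a
#' repeatability figure — by default the pooled within-sample standard
#' deviation of the replicates, optionally the ISO repeatability limit
#' \code{r = 2.8 * SD}.
#'
#' @param table \code{data.frame} with columns \code{sample_id},
#'   \code{element}, \code{ppm}; >= 1 replicate per sample
#' @param isoLimit if TRUE report \code{2.8 *} the pooled SD (default
#'   FALSE)
#' @return \code{data.frame} with columns \code{element}, \code{min},
#'   \code{max}, \code{mean}, \code{median}, \code{repeatability} (ppm)
#' @export
summarizeMeasurements <- function(table, isoLimit = FALSE) {
    need <- c("sample_id", "element", "ppm")
    stopifnot(all(need %in% colnames(table)))
    out <- lapply(split(table, table$element), function(sub) {
        bySample <- split(sub$ppm, sub$sample_id)
        means <- vapply(bySample, mean, 0)
        # pooled SD: sqrt(sum of within-sample SS / sum of (n_i - 1))
        ss <- vapply(bySample, function(v) sum((v - mean(v))^2), 0)
        df <- vapply(bySample, function(v) length(v) - 1L, 0L)
        rep <- if (sum(df) > 0) sqrt(sum(ss) / sum(df)) else 0
        data.frame(element = sub$element[1L],
                   min = min(means), max = max(means),
                   mean = mean(means), median = stats::median(means),
                   repeatability = if (isoLimit) 2.8 * rep else rep,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Percent recovery against a certified reference material
#'
#' \code{\%R = 100 * measured / certified}; measured and certified must
#' share units.
#'
#' @param measured measured concentration(s)
#' @param certified certified value(s), nonzero
#' @return recovery in percent
#' @examples
#' percentRecovery(13.32, 13.9)   # 95.83 %
#' @export
percentRecovery <- function(measured, certified) {
    if (any(certified == 0)) stop("certified value must be nonzero")
    100 * measured / certified
}
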