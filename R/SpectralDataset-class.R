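#' SpectralDataset: Raman spectra on a shared shift axis
#'
#' An S4 container for a set of Raman spectra that share one ascending
#' Raman-shift axis. It extends
#' \linkS4class{SummarizedExperiment}: spectral channels are rows (the
#' shift, in cm^-1, lives in \code{rowData()$shift}), scans or samples are
#' columns, and per-scan metadata (\code{sample_id}, \code{replicate_id},
#' optionally \code{formula_id} and \code{powder_pct}) lives in
#' \code{colData()}. The single assay, \code{"intensity"}, holds counts
#' per second.
#'
#' Validity requires a strictly increasing finite axis, all-finite
#' intensities, at least two channels, and a \code{sample_id} column.
#'
#' @seealso [readSpectraTable()], [averageReplicates()], [cropRegion()],
#'   [simulateDataset()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass SpectralDataset
setClass("SpectralDataset", contains = "SummarizedExperiment")

setValidity("SpectralDataset", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!"shift" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain a 'shift' column (cm^-1)")
    } else {
        shift <- rd$shift
        if (!is.numeric(shift) || anyNA(shift) || any(!is.finite(shift)))
            msg <- c(msg, "shift axis must be finite numeric")
        else if (length(shift) >= 2L && any(diff(shift) <= 0))
            msg <- c(msg, "shift axis must be strictly increasing")
        if (length(shift) < 2L)
            msg <- c(msg, "at least 2 spectral channels are required")
    }
    if (!"sample_id" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain 'sample_id'")
    a <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(a) || any(!is.finite(a)))
        msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectralDataset
#'
#' @param intensities numeric matrix of intensities, samples in rows and
#'   channels in columns (cps). A single spectrum may be given as a vector.
#' @param shift numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, one per channel.
#' @param sampleIds character vector of sample identifiers, one per row of
#'   \code{intensities}.
#' @param replicateIds character vector of replicate identifiers
#'   (default \code{"1"}).
#' @param meta optional \code{data.frame} of additional per-scan metadata
#'   (e.g. \code{formula_id}, \code{powder_pct}).
#' @return a \linkS4class{SpectralDataset}
#' @examples
#' sd <- SpectralDataset(rbind(c(1, 2, 3), c(3, 2, 1)),
#'                       shift = c(100, 200, 300),
#'                       sampleIds = c("A", "B"))
#' shiftAxis(sd)
#' @export
SpectralDataset <- function(intensities, shift, sampleIds,
                            replicateIds = NULL, meta = NULL) {
    if (is.null(dim(intensities)))
        intensities <- matrix(intensities, nrow = 1L)
    intensities <- as.matrix(intensities)
    if (ncol(intensities) != length(shift))
        stop("ncol(intensities) must equal length(shift)")
    if (nrow(intensities) != length(sampleIds))
        stop("nrow(intensities) must equal length(sampleIds)")
    if (is.null(replicateIds))
        replicateIds <- rep("1", nrow(intensities))
    cd <- S4Vectors::DataFrame(sample_id = as.character(sampleIds),
                               replicate_id = as.character(replicateIds))
    if (!is.null(meta)) {
        meta <- as.data.frame(meta)
        for (nm in setdiff(colnames(meta), colnames(cd)))
            cd[[nm]] <- meta[[nm]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = t(unname(intensities))),
        rowData = S4Vectors::DataFrame(shift = as.numeric(shift)),
        colData = cd)
    methods::new("SpectralDataset", se)
}

#' @describeIn SpectralDataset the Raman-shift axis (cm^-1)
#' @param x,object a \code{SpectralDataset}
#' @export
shiftAxis <- function(x) SummarizedExperiment::rowData(x)$shift

#' @describeIn SpectralDataset intensity matrix, samples x channels (cps)
#' @export
intensityMatrix <- function(x) {
    m <- t(SummarizedExperiment::assay(x, "intensity"))
    rownames(m) <- x$sample_id
    m
}

#' @describeIn SpectralDataset per-scan sample identifiers
#' @export
sampleIds <- function(x) x$sample_id

#' @export
setMethod("show", "SpectralDataset", function(object) {
    ax <- shiftAxis(object)
    cat(sprintf("SpectralDataset: %d scan(s) x %d channels, %g-%g cm^-1\n",
                ncol(object), nrow(object), min(ax), max(ax)))
    cat(sprintf("  samples: %d unique sample_id(s)\n",
                length(unique(object$sample_id))))
    extra <- setdiff(colnames(SummarizedExperiment::colData(object)),
                     c("sample_id", "replicate_id"))
    if (length(extra))
        cat("  metadata:", paste(extra, collapse = ", "), "\n")
})

#' Average replicate scans into one spectrum per sample
#'
#' Replicate scans sharing a \code{sample_id} are reduced to their
#' arithmetic mean, mirroring the use of the averaged duplicate spectrum
#' in downstream calibration. The operation is idempotent. Per-sample
#' metadata is taken from the first scan of each sample; sample order of
#' first appearance is preserved.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @return a \code{SpectralDataset} with one column per unique sample
#' @export
averageReplicates <- function(dataset) {
    stopifnot(methods::is(dataset, "SpectralDataset"))
    ids <- dataset$sample_id
    uniq <- unique(ids)
    a <- SummarizedExperiment::assay(dataset, "intensity")
    out <- vapply(uniq, function(s) rowMeans(a[, ids == s, drop = FALSE]),
                  numeric(nrow(a)))
    cd <- SummarizedExperiment::colData(dataset)
    cd <- cd[match(uniq, ids), , drop = FALSE]
    cd$replicate_id <- "mean"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = out),
        rowData = SummarizedExperiment::rowData(dataset),
        colData = cd)
    methods::new("SpectralDataset", se)
}

#' Crop a spectral dataset to a shift window
#'
#' Keeps channels with \code{lo <= shift <= hi} (closed interval, so both
#' stated endpoints of a range such as 50-1800 cm^-1 are retained).
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param lo,hi window bounds in cm^-1, \code{lo < hi}
#' @return the cropped \code{SpectralDataset}
#' @export
cropRegion <- function(dataset, lo, hi) {
    stopifnot(methods::is(dataset, "SpectralDataset"), lo < hi)
    keep <- which(shiftAxis(dataset) >= lo & shiftAxis(dataset) <= hi)
    if (length(keep) < 2L)
        stop(sprintf("crop window [%g, %g] leaves fewer than 2 channels",
                     lo, hi))
    dataset[keep, ]
}
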