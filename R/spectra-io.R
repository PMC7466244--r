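#' Read a spectral table from CSV
#'
#' Two plain-text dialects are supported (comma separator, "." decimal,
#' UTF-8):
#' \describe{
#'   \item{wide}{first column is the shift axis (cm^-1); every further
#'     column is one scan. Column headers of the form
#'     \code{"<sample>__<replicate>"} carry the replicate identity;
#'     headers without \code{"__"} get replicate \code{"1"}.}
#'   \item{long}{records with columns \code{sample_id}, \code{replicate_id},
#'     \code{shift}, \code{intensity}; every scan must cover the same axis.}
#' }
#' A descending axis is accepted and reversed (intensities re-ordered
#' consistently); a non-monotone or duplicated axis is a format error.
#' Replicates are \emph{not} averaged here — see [averageReplicates()].
#'
#' @param path path to the CSV file
#' @param layout \code{"wide"} or \code{"long"}
#' @return a \linkS4class{SpectralDataset} with one column per scan
#' @export
readSpectraTable <- function(path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (layout == "wide") {
        if (ncol(tab) < 2L) stop("wide layout needs an axis column and at least one scan")
        shift <- tab[[1L]]
        if (!is.numeric(shift)) stop("axis column must be numeric")
        ints <- as.matrix(tab[, -1L, drop = FALSE])
        if (!is.numeric(ints)) stop("intensity columns must be numeric")
        scan <- colnames(tab)[-1L]
        parts <- strsplit(scan, "__", fixed = TRUE)
        sid <- vapply(parts, `[`, "", 1L)
        rid <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "1", "")
    } else {
        need <- c("sample_id", "replicate_id", "shift", "intensity")
        if (!all(need %in% colnames(tab)))
            stop("long layout needs columns: ", paste(need, collapse = ", "))
        key <- paste(tab$sample_id, tab$replicate_id, sep = "__")
        scans <- unique(key)
        shift <- tab$shift[key == scans[1L]]
        ints <- vapply(scans, function(k) {
            sub <- tab[key == k, ]
            if (length(sub$shift) != length(shift) ||
                any(sub$shift != shift))
                stop("long layout: scans do not share one axis")
            sub$intensity
        }, numeric(length(shift)))
        parts <- strsplit(scans, "__", fixed = TRUE)
        sid <- vapply(parts, `[`, "", 1L)
        rid <- vapply(parts, `[`, "", 2L)
    }
    d <- diff(shift)
    if (any(d == 0)) stop("format error: duplicated axis values")
    if (all(d < 0)) {            # descending file: reverse to ascending
        shift <- rev(shift)
        ints <- ints[rev(seq_along(shift)), , drop = FALSE]
    } else if (any(d < 0)) {
        stop("format error: axis is not monotone")
    }
    SpectralDataset(t(ints), shift = shift, sampleIds = sid,
                    replicateIds = rid)
}

#' Write a spectral dataset to CSV
#'
#' Inverse of [readSpectraTable()]; a read-write-read round trip through
#' the wide dialect reproduces intensities bit-exactly (values are written
#' with full double precision).
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param path output path
#' @param layout \code{"wide"} or \code{"long"}
#' @return \code{path}, invisibly
#' @export
writeSpectraTable <- function(dataset, path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    m <- SummarizedExperiment::assay(dataset, "intensity")
    key <- paste(dataset$sample_id, dataset$replicate_id, sep = "__")
    if (layout == "wide") {
        out <- data.frame(shift = shiftAxis(dataset), m,
                          check.names = FALSE)
        colnames(out) <- c("shift", key)
    } else {
        out <- data.frame(
            sample_id = rep(dataset$sample_id, each = nrow(m)),
            replicate_id = rep(dataset$replicate_id, each = nrow(m)),
            shift = rep(shiftAxis(dataset), ncol(m)),
            intensity = as.vector(m))
    }
    utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a reference concentration table
#'
#' Expects a CSV with columns \code{sample_id}, \code{element},
#' \code{ppm} and optionally \code{repeatability} (ppm). Concentrations
#' must be finite; negative values are allowed (below-detection
#' artifacts are passed through, flagged by [summarizeMeasurements()]'s
#' caller if desired).
#'
#' @param path path to the CSV file
#' @return a \code{data.frame} with one row per (sample, element)
#' @export
readReferenceTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "element", "ppm")
    if (!all(need %in% colnames(tab)))
        stop("reference table needs columns: ", paste(need, collapse = ", "))
    if (anyNA(tab$ppm) || any(!is.finite(tab$ppm)))
        stop("reference concentrations must be finite")
    tab
}

#' Align a reference table with a spectral dataset
#'
#' Returns the reference vector (ppm) for one element, ordered to match
#' the dataset's samples; errors if any sample lacks a value.
#'
#' @param dataset a \linkS4class{SpectralDataset} (one column per sample)
#' @param references a reference \code{data.frame} as from
#'   [readReferenceTable()]
#' @param element element symbol, e.g. \code{"Ca"}
#' @return named numeric vector of concentrations (ppm)
#' @export
referenceVector <- function(dataset, references, element) {
    sub <- references[references$element == element, ]
    if (!nrow(sub)) stop("element not present in reference table: ", element)
    idx <- match(dataset$sample_id, sub$sample_id)
    if (anyNA(idx))
        stop("reference values missing for sample(s): ",
             paste(dataset$sample_id[is.na(idx)], collapse = ", "))
    stats::setNames(sub$ppm[idx], dataset$sample_id)
}
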