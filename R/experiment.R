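#' Quasi-random calibration/validation split
#'
#' Rank-stratified alternation over the response: samples are ranked by
#' \code{y}; the global minimum and maximum are forced into the
#' calibration set (so validation never extrapolates); the remaining
#' ranks are walked in order and assigned alternately to calibration and
#' validation, with a seeded random swap inside each consecutive pair
#' (the "quasi-random" jitter); finally the assignment is trimmed or
#' topped up, farthest-from-extremes first, until the sizes are exactly
#' \code{(nCal, n - nCal)}. Deterministic given \code{seed}.
#'
#' @param y response vector (ppm)
#' @param nCal calibration set size, \code{2 <= nCal < length(y)}
#' @param seed integer seed
#' @return list with integer index vectors \code{cal} and \code{val}
#' @export
quasiRandomSplit <- function(y, nCal, seed = 1L) {
    n <- length(y)
    stopifnot(nCal >= 2L, nCal < n)
    ord <- order(y)
    forced <- c(ord[1L], ord[n])
    rest <- ord[-c(1L, n)]
    set.seed(seed)
    inCal <- logical(length(rest))
    i <- 1L
    while (i <= length(rest)) {
        if (i < length(rest) && stats::runif(1) < 0.5) {
            inCal[i] <- FALSE; inCal[i + 1L] <- TRUE   # swapped pair
        } else {
            inCal[i] <- TRUE
            if (i < length(rest)) inCal[i + 1L] <- FALSE
        }
        i <- i + 2L
    }
    cal <- c(forced, rest[inCal])
    val <- rest[!inCal]
    ## adjust sizes deterministically, moving mid-rank samples first
    while (length(cal) > nCal) {
        move <- cal[length(cal)]
        cal <- cal[-length(cal)]
        val <- c(val, move)
    }
    while (length(cal) < nCal) {
        move <- val[length(val)]
        val <- val[-length(val)]
        cal <- c(cal, move)
    }
    list(cal = sort(cal), val = sort(val))
}

#' Pipeline configuration
#'
#' One fully specified modeling run: pre-treatment, spectral region,
#' target element, model complexity cap, venetian-blind splits, optional
#' variable selection, optional calibration/validation split, optional
#' outlier exclusion.
#'
#' @param preprocess a [preprocessConfig()]
#' @param region numeric \code{c(lo, hi)} in cm^-1
#' @param element element symbol present in the reference table
#' @param AMax latent-variable cap (default 6)
#' @param forceA force this exact component count instead of the
#'   parsimony rule (NA = choose by RMSECV)
#' @param cvSplits venetian-blind split count (default 10)
#' @param selection optional selection method (\code{"vip"},
#'   \code{"smc"}, \code{"martens"}) or NA for none
#' @param vipThreshold VIP retention cutoff (default 1)
#' @param alpha significance level for smc/martens selection
#' @param nCal optional calibration size for a split design (NA = use
#'   all samples for calibration and cross-validation)
#' @param splitSeed seed of the quasi-random split
#' @param splitIndices optional explicit split, a list with integer
#'   vectors \code{cal} and \code{val} (positions after exclusion);
#'   overrides \code{nCal}/\code{splitSeed}
#' @param exclude character vector of sample_ids to drop before
#'   modeling (explicit outlier list; never automatic)
#' @param label optional data-type label for report rows (defaults to
#'   the preprocessing method)
#' @return a list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(preprocess = preprocessConfig("asls"),
                           region = c(50, 3398), element, AMax = 6L,
                           forceA = NA_integer_, cvSplits = 10L,
                           selection = NA_character_, vipThreshold = 1,
                           alpha = 0.05, nCal = NA_integer_,
                           splitSeed = 1L, splitIndices = NULL,
                           exclude = character(), label = NULL) {
    stopifnot(inherits(preprocess, "PreprocessConfig"),
              length(region) == 2L, region[1L] < region[2L],
              is.character(element), AMax >= 1L, cvSplits >= 2L)
    if (!is.na(selection))
        selection <- match.arg(selection, c("vip", "smc", "martens"))
    structure(list(preprocess = preprocess, region = region,
                   element = element, AMax = as.integer(AMax),
                   forceA = as.integer(forceA),
                   cvSplits = as.integer(cvSplits),
                   selection = selection, vipThreshold = vipThreshold,
                   alpha = alpha, nCal = as.integer(nCal),
                   splitSeed = as.integer(splitSeed),
                   splitIndices = splitIndices,
                   exclude = exclude,
                   label = if (is.null(label)) preprocess$method
                           else label),
              class = "PipelineConfig")
}

#' Run one modeling pipeline and fill a report row
#'
#' Stages, mirroring the study workflow: replicate averaging (if the
#' dataset still holds per-scan columns), pre-treatment, cropping to the
#' configured region, optional outlier exclusion, optional quasi-random
#' calibration/validation split, venetian-blinds cross-validated PLS1
#' fit, optional one-pass variable selection plus refit, and (in a split
#' design) prediction of the held-out validation samples. Validation
#' rows never enter centering, selection or component choice.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param references reference \code{data.frame} (\code{sample_id},
#'   \code{element}, \code{ppm})
#' @param config a [pipelineConfig()]
#' @param preprocessed set TRUE if \code{dataset} has already been
#'   pre-treated (the stage is then skipped; used by [runGrid()] to
#'   share one pre-treatment across configurations)
#' @return one-row \code{data.frame} (a ModelReport): \code{element},
#'   \code{data_type}, \code{region}, \code{n_cal}, \code{n_val},
#'   \code{spectral_variables}, \code{A}, \code{R2C}, \code{RMSEC},
#'   \code{R2CV}, \code{RMSECV}, \code{bias_cv}, \code{R2P},
#'   \code{RMSEP}, \code{bias_p} (prediction columns NA without a split)
#' @export
evaluatePipeline <- function(dataset, references, config,
                             preprocessed = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    stage <- "replicate averaging"
    out <- tryCatch({
        ds <- if (anyDuplicated(dataset$sample_id))
                  averageReplicates(dataset) else dataset
        stage <- "preprocessing"
        if (!preprocessed)
            ds <- preprocessDataset(ds, config$preprocess)
        stage <- "cropping"
        ds <- cropRegion(ds, config$region[1L], config$region[2L])
        stage <- "reference alignment"
        if (length(config$exclude))
            ds <- ds[, !ds$sample_id %in% config$exclude]
        y <- referenceVector(ds, references, config$element)
        X <- intensityMatrix(ds)
        stage <- "calibration/validation split"
        if (!is.null(config$splitIndices) || !is.na(config$nCal)) {
            sp <- if (!is.null(config$splitIndices)) config$splitIndices
                  else quasiRandomSplit(y, config$nCal, config$splitSeed)
            Xval <- X[sp$val, , drop = FALSE]; yval <- y[sp$val]
            X <- X[sp$cal, , drop = FALSE];    y <- y[sp$cal]
        } else {
            Xval <- NULL; yval <- NULL
        }
        stage <- "cross-validation"
        AMax <- min(config$AMax, nrow(X) - 1L, ncol(X))
        predictCal <- NULL
        if (!is.na(config$selection)) {
            stage <- paste0("selection (", config$selection, ")")
            sr <- selectAndRefit(X, y, method = config$selection,
                                 A = AMax, s = config$cvSplits,
                                 threshold = config$vipThreshold,
                                 alpha = config$alpha)
            cv <- sr$cv; model <- sr$model
            nVar <- nSelected(sr$selection)
            keep <- sr$selection@selected
        } else {
            cv <- crossValidate(X, y, AMax = AMax, s = config$cvSplits)
            model <- fitPLS1(X, y, AMax)
            nVar <- ncol(X)
            keep <- seq_len(ncol(X))
        }
        A <- if (!is.na(config$forceA)) min(config$forceA, model@A)
             else cv$chosenA
        stage <- "metrics"
        calPred <- predict(model, X[, keep, drop = FALSE], a = A)
        mc <- regressionMetrics(y, calPred, "calibration")
        mcv <- regressionMetrics(y, cv$cvPredictions[, A],
                                 "cross_validation")
        if (!is.null(Xval)) {
            stage <- "validation prediction"
            valPred <- predict(model, Xval[, keep, drop = FALSE], a = A)
            mp <- regressionMetrics(yval, valPred, "prediction")
        } else {
            mp <- data.frame(r2 = NA_real_, rmse = NA_real_,
                             bias = NA_real_)
        }
        data.frame(element = config$element,
                   data_type = config$label,
                   region = paste0(config$region[1L], "-",
                                   config$region[2L]),
                   n_cal = nrow(X),
                   n_val = if (is.null(Xval)) 0L else nrow(Xval),
                   spectral_variables = nVar, A = A,
                   R2C = mc$r2, RMSEC = mc$rmse,
                   R2CV = mcv$r2, RMSECV = mcv$rmse,
                   bias_cv = mcv$bias,
                   R2P = mp$r2, RMSEP = mp$rmse, bias_p = mp$bias,
                   stringsAsFactors = FALSE)
    }, error = function(e)
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE))
    out
}

#' Evaluate a grid of pipeline configurations
#'
#' Each configuration is evaluated independently; a failing
#' configuration becomes a row-level error message and the run
#' continues. The per-element best model (lowest RMSECV, ties broken by
#' fewer components) is marked in the \code{best} column — the analog of
#' the bold rows of a summary table.
#'
#' @param dataset a \linkS4class{SpectralDataset}
#' @param references reference \code{data.frame}
#' @param configs non-empty list of [pipelineConfig()]s
#' @return \code{data.frame} of report rows with \code{best} and
#'   \code{error} columns
#' @export
runGrid <- function(dataset, references, configs) {
    if (!length(configs)) stop("empty configuration list")
    ## replicate averaging and pre-treatment depend only on the
    ## preprocessing settings, so share them across configs
    averaged <- if (anyDuplicated(dataset$sample_id))
                    averageReplicates(dataset) else dataset
    ppCache <- new.env(parent = emptyenv())
    rows <- lapply(configs, function(cfg) {
        tryCatch({
            key <- paste(deparse(cfg$preprocess), collapse = "")
            if (is.null(ppCache[[key]]))
                ppCache[[key]] <- preprocessDataset(averaged,
                                                    cfg$preprocess)
            r <- evaluatePipeline(ppCache[[key]], references, cfg,
                                  preprocessed = TRUE)
            r$error <- NA_character_
            r
        }, error = function(e)
            data.frame(element = cfg$element, data_type = cfg$label,
                       region = paste0(cfg$region[1L], "-",
                                       cfg$region[2L]),
                       n_cal = NA_integer_, n_val = NA_integer_,
                       spectral_variables = NA_integer_,
                       A = NA_integer_, R2C = NA_real_, RMSEC = NA_real_,
                       R2CV = NA_real_, RMSECV = NA_real_,
                       bias_cv = NA_real_, R2P = NA_real_,
                       RMSEP = NA_real_, bias_p = NA_real_,
                       error = conditionMessage(e),
                       stringsAsFactors = FALSE))
    })
    tab <- do.call(rbind, rows)
    tab$best <- FALSE
    for (el in unique(tab$element)) {
        idx <- which(tab$element == el & !is.na(tab$RMSECV))
        if (!length(idx)) next
        o <- idx[order(tab$RMSECV[idx], tab$A[idx])]
        tab$best[o[1L]] <- TRUE
    }
    rownames(tab) <- NULL
    tab
}

#' Write a report table as CSV and aligned text
#'
#' @param report a \code{data.frame} from [runGrid()] or
#'   [evaluatePipeline()]
#' @param path output path without extension; writes \code{<path>.csv}
#'   and \code{<path>.txt}
#' @return invisibly, the two paths written
#' @export
writeReportTable <- function(report, path) {
    csv <- paste0(path, ".csv")
    txt <- paste0(path, ".txt")
    utils::write.csv(report, csv, row.names = FALSE)
    num <- vapply(report, is.numeric, TRUE)
    pretty <- report
    pretty[num] <- lapply(report[num], function(v) signif(v, 4))
    writeLines(utils::capture.output(print(pretty, row.names = FALSE)),
               txt)
    invisible(c(csv, txt))
}
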