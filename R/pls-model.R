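#' PLSModel: a centered PLS1 decomposition
#'
#' Holds the NIPALS PLS1 decomposition of a centered calibration set:
#' unit-norm weight vectors \code{W} (channels x A), x-loadings \code{P},
#' mutually orthogonal score vectors \code{T} (samples x A), inner
#' regression coefficients \code{q} (length A), and the
#' regression-coefficient matrix \code{B} whose column \code{a} is the
#' coefficient vector of the \code{a}-component model. \code{xMean} and
#' \code{yMean} are the centering statistics; predictions are
#' \code{yMean + (X - xMean) \%*\% B[, a]}.
#'
#' @slot xMean numeric, per-channel mean of the calibration predictors
#' @slot yMean numeric(1), calibration response mean
#' @slot W,P numeric matrices, channels x A
#' @slot T numeric matrix, samples x A
#' @slot q numeric, length A
#' @slot B numeric matrix, channels x A
#' @slot A integer, number of latent variables
#' @exportClass PLSModel
setClass("PLSModel",
         representation(xMean = "numeric", yMean = "numeric",
                        W = "matrix", P = "matrix", T = "matrix",
                        q = "numeric", B = "matrix", A = "integer"))

setValidity("PLSModel", function(object) {
    A <- object@A
    if (ncol(object@W) != A || ncol(object@P) != A ||
        ncol(object@T) != A || length(object@q) != A ||
        ncol(object@B) != A)
        return("W, P, T, q, B must all have A components")
    nrm <- sqrt(colSums(object@W^2))
    if (any(abs(nrm - 1) > 1e-8))
        return("columns of W must be unit-norm")
    TRUE
})

#' @export
setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel: %d latent variable(s), %d channels, %d samples\n",
                object@A, nrow(object@W), nrow(object@T)))
})

#' Fit a PLS1 regression by NIPALS
#'
#' After mean-centering X and y, each component is extracted as
#' \code{w = X'y / ||X'y||}, \code{t = X w}, \code{p = X't / t't},
#' \code{q = y't / t't}, followed by deflation \code{X <- X - t p'},
#' \code{y <- y - q t}. Regression-coefficient vectors for every
#' component count \code{a = 1..A} are stored
#' (\code{B_a = W_a (P_a' W_a)^{-1} q_a}). Intensities are used on their
#' native scale: mean-centering only, no unit-variance scaling (the
#' channels share units).
#'
#' @param X numeric matrix, samples x channels
#' @param y numeric response vector (ppm), non-constant
#' @param A number of latent variables, \code{<= min(n - 1, channels)}
#' @param center logical; mean-center X and y (default TRUE)
#' @return a \linkS4class{PLSModel}
#' @export
fitPLS1 <- function(X, y, A, center = TRUE) {
    X <- as.matrix(X)
    n <- nrow(X); J <- ncol(X)
    stopifnot(length(y) == n)
    if (stats::sd(y) == 0) stop("response has zero variance")
    if (A > min(n - 1L, J))
        stop(sprintf("A = %d exceeds min(n - 1, channels) = %d",
                     A, min(n - 1L, J)))
    xMean <- if (center) colMeans(X) else numeric(J)
    yMean <- if (center) mean(y) else 0
    Xc <- sweep(X, 2L, xMean)
    yc <- y - yMean
    W <- P <- matrix(0, J, A)
    Tm <- matrix(0, n, A)
    q <- numeric(A)
    for (a in seq_len(A)) {
        w <- crossprod(Xc, yc)
        nw <- sqrt(sum(w^2))
        if (nw < .Machine$double.eps * J)
            stop(sprintf("X'y vanished at component %d: reduce A", a))
        w <- w / nw
        t <- as.numeric(Xc %*% w)
        tt <- sum(t^2)
        p <- as.numeric(crossprod(Xc, t)) / tt
        q[a] <- sum(yc * t) / tt
        Xc <- Xc - tcrossprod(t, p)
        yc <- yc - q[a] * t
        W[, a] <- w; P[, a] <- p; Tm[, a] <- t
    }
    R <- crossprod(P, W)                 # upper-triangular, unit-free
    B <- vapply(seq_len(A), function(a)
        as.numeric(W[, seq_len(a), drop = FALSE] %*%
                   solve(R[seq_len(a), seq_len(a), drop = FALSE],
                         q[seq_len(a)])),
        numeric(J))
    B <- matrix(B, nrow = J)
    methods::new("PLSModel", xMean = xMean, yMean = yMean,
                 W = W, P = P, T = Tm, q = q, B = B, A = as.integer(A))
}

#' Predict from a PLSModel
#'
#' \code{yhat = yMean + (X - xMean) B_a}.
#'
#' @param object a \linkS4class{PLSModel}
#' @param X matrix of new spectra, samples x channels (channel count must
#'   match the calibration set)
#' @param a component count to use (default: all fitted components)
#' @param ... ignored
#' @return numeric vector of predictions (ppm)
#' @export
setMethod("predict", "PLSModel", function(object, X, a = object@A, ...) {
    X <- as.matrix(X)
    if (ncol(X) != nrow(object@B))
        stop(sprintf("channel mismatch: model has %d, input has %d",
                     nrow(object@B), ncol(X)))
    stopifnot(a >= 1L, a <= object@A)
    as.numeric(object@yMean +
               sweep(X, 2L, object@xMean) %*% object@B[, a])
})

#' Venetian-blinds fold assignment
#'
#' Sample \code{i} (1-based, dataset order) goes to fold
#' \code{((i - 1) mod s) + 1}: every \code{s}-th sample shares a fold.
#' Deterministic by construction; \code{s = n} gives leave-one-out.
#'
#' @param n number of samples
#' @param s number of splits, \code{2 <= s <= n}
#' @return integer vector of fold ids in \code{1..s}
#' @export
venetianBlindsIndices <- function(n, s) {
    stopifnot(s >= 2L, s <= n)
    ((seq_len(n) - 1L) %% as.integer(s)) + 1L
}

#' Regression performance metrics
#'
#' \code{rmse = sqrt(mean((yhat - y)^2))},
#' \code{r2 = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)},
#' \code{bias = mean(yhat - y)}. These are the calibration (RMSEC/R2C),
#' cross-validation (RMSECV/R2CV) and prediction (RMSEP/R2P) columns,
#' depending on \code{context}.
#'
#' @param yRef reference values (ppm)
#' @param yHat predicted values (ppm)
#' @param context one of \code{"calibration"}, \code{"cross_validation"},
#'   \code{"prediction"}
#' @return one-row \code{data.frame} with \code{r2}, \code{rmse},
#'   \code{bias}, \code{context}
#' @export
regressionMetrics <- function(yRef, yHat,
                              context = c("calibration",
                                          "cross_validation",
                                          "prediction")) {
    context <- match.arg(context)
    stopifnot(length(yRef) == length(yHat), length(yRef) > 0)
    ssTot <- sum((yRef - mean(yRef))^2)
    if (ssTot == 0) stop("zero variance in reference values: r2 undefined")
    res <- yHat - yRef
    data.frame(r2 = 1 - sum(res^2) / ssTot,
               rmse = sqrt(mean(res^2)),
               bias = mean(res),
               context = context,
               stringsAsFactors = FALSE)
}

#' Venetian-blinds cross-validation of a PLS1 model
#'
#' For each fold, a model is fit on the complement (centering recomputed
#' on the training rows only — no information leaks from the held-out
#' rows) and the held-out rows are predicted at every component count
#' \code{1..AMax}. Out-of-fold predictions cover each sample exactly
#' once. The retained component count \code{chosenA} is the smallest
#' \code{a} whose RMSECV is within \code{(1 + tolParsimony)} of the
#' minimum over \code{a} — a parsimony rule favouring small models.
#'
#' @param X matrix, samples x channels
#' @param y response vector (ppm)
#' @param AMax maximum component count (must fit the smallest training fold)
#' @param s number of venetian-blind splits (default 10)
#' @param tolParsimony relative RMSECV slack for choosing a smaller model
#'   (default 0.02)
#' @param center mean-center per training fold (default TRUE)
#' @return a list of class \code{"CVResult"}: \code{rmsecv}, \code{r2cv},
#'   \code{bias} (vectors over \code{a}), \code{chosenA},
#'   \code{cvPredictions} (matrix samples x AMax), \code{splits}
#' @export
crossValidate <- function(X, y, AMax, s = 10L, tolParsimony = 0.02,
                          center = TRUE) {
    X <- as.matrix(X)
    n <- nrow(X)
    folds <- venetianBlindsIndices(n, s)
    minTrain <- n - max(tabulate(folds, nbins = s))
    if (minTrain < 2L) stop("a fold leaves fewer than 2 training samples")
    if (AMax > min(minTrain - 1L, ncol(X)))
        stop("AMax too large for the smallest training fold")
    pred <- matrix(NA_real_, n, AMax)
    for (f in seq_len(s)) {
        hold <- folds == f
        fit <- fitPLS1(X[!hold, , drop = FALSE], y[!hold], AMax,
                       center = center)
        for (a in seq_len(AMax))
            pred[hold, a] <- predict(fit, X[hold, , drop = FALSE], a = a)
    }
    met <- lapply(seq_len(AMax), function(a)
        regressionMetrics(y, pred[, a], "cross_validation"))
    met <- do.call(rbind, met)
    chosenA <- which(met$rmse <= (1 + tolParsimony) * min(met$rmse))[1L]
    structure(list(rmsecv = met$rmse, r2cv = met$r2, bias = met$bias,
                   chosenA = as.integer(chosenA),
                   cvPredictions = pred, splits = folds),
              class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
    cat(sprintf("CVResult: %d fold(s), chosen A = %d (RMSECV %.4g, R2CV %.3f)\n",
                max(x$splits), x$chosenA, x$rmsecv[x$chosenA],
                x$r2cv[x$chosenA]))
    invisible(x)
}
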