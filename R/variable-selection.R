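#' SelectionResult: per-channel importance with a retention rule
#'
#' @slot method \code{"vip"}, \code{"smc"} or \code{"martens"}
#' @slot scores per-channel importance (VIP score, sMC F statistic, or
#'   Martens t statistic)
#' @slot threshold the retention threshold actually applied (VIP cutoff
#'   or the critical value at \code{alpha})
#' @slot selected integer indices of the retained channels
#' @slot alpha significance level for smc/martens (NA for vip)
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(method = "character", scores = "numeric",
                        threshold = "numeric", selected = "integer",
                        alpha = "numeric"))

setValidity("SelectionResult", function(object) {
    if (!object@method %in% c("vip", "smc", "martens"))
        return("method must be vip, smc or martens")
    if (length(object@selected) &&
        (min(object@selected) < 1L ||
         max(object@selected) > length(object@scores)))
        return("selected indices out of range")
    TRUE
})

#' @export
setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult (%s): %d of %d channels retained (threshold %.4g)\n",
                object@method, length(object@selected),
                length(object@scores), object@threshold))
})

#' @describeIn selectAndRefit number of retained channels
#' @export
nSelected <- function(selection) length(selection@selected)

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{ J \sum_{k \le a} q_k^2 (t_k' t_k) (w_{jk}/\|w_k\|)^2
#'   / \sum_{k \le a} q_k^2 (t_k' t_k) }}
#' with \eqn{J} the channel count. By construction the mean of the
#' squared scores over channels is exactly 1, so the conventional cutoff
#' of 1 retains channels with greater-than-average influence. VIP is
#' invariant to positive rescaling of the response.
#'
#' @param model a fitted \linkS4class{PLSModel}
#' @param a number of components to accumulate (default: all)
#' @return numeric vector of VIP scores, one per channel
#' @export
vipScores <- function(model, a = model@A) {
    stopifnot(methods::is(model, "PLSModel"), a >= 1L, a <= model@A)
    J <- nrow(model@W)
    ssy <- model@q[seq_len(a)]^2 *
        colSums(model@T[, seq_len(a), drop = FALSE]^2)
    W2 <- sweep(model@W[, seq_len(a), drop = FALSE]^2, 2L,
                colSums(model@W[, seq_len(a), drop = FALSE]^2), "/")
    sqrt(J * as.numeric(W2 %*% ssy) / sum(ssy))
}

#' Select channels by VIP score
#'
#' @param model a fitted \linkS4class{PLSModel}
#' @param a components to accumulate (default: all)
#' @param threshold retention cutoff; channels with
#'   \code{VIP > threshold} are kept (default 1, the
#'   greater-than-average-influence convention)
#' @return a \linkS4class{SelectionResult}
#' @export
vipSelect <- function(model, a = model@A, threshold = 1) {
    v <- vipScores(model, a)
    methods::new("SelectionResult", method = "vip", scores = v,
                 threshold = threshold,
                 selected = which(v > threshold), alpha = NA_real_)
}

#' Significance multivariate correlation (sMC)
#'
#' Each mean-centered channel \eqn{x_j} is regressed on the model's
#' fitted response \eqn{\hat y}; the per-channel statistic is the
#' one-regressor F ratio
#' \eqn{F_j = SS_{reg,j} / (SS_{res,j} / (n - 2))}. Channels whose
#' \eqn{F_j} exceeds the \eqn{F(1, n-2)} critical value at \code{alpha}
#' are flagged. A channel exactly proportional to \eqn{\hat y} has zero
#' residual; its statistic is capped at \code{.Machine$double.xmax} and
#' flagged significant.
#'
#' @param model a fitted \linkS4class{PLSModel}
#' @param X calibration matrix, samples x channels
#' @param y calibration response (unused beyond dimension checks; the
#'   test is against the fitted response)
#' @param alpha significance level (default 0.05)
#' @param a component count for the fitted response (default: all)
#' @return a \linkS4class{SelectionResult} with F statistics as scores
#' @export
smcScores <- function(model, X, y, alpha = 0.05, a = model@A) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n <= 2L) stop("sMC needs more than 2 samples")
    yhat <- predict(model, X, a = a)
    yc <- yhat - mean(yhat)
    Xc <- sweep(X, 2L, colMeans(X))
    syy <- sum(yc^2)
    beta <- as.numeric(crossprod(Xc, yc)) / syy
    ssReg <- beta^2 * syy
    ssTot <- colSums(Xc^2)
    ssRes <- pmax(ssTot - ssReg, 0)
    Fj <- ifelse(ssRes <= .Machine$double.eps * ssTot,
                 .Machine$double.xmax,
                 ssReg / (ssRes / (n - 2)))
    crit <- stats::qf(1 - alpha, 1, n - 2)
    methods::new("SelectionResult", method = "smc", scores = Fj,
                 threshold = crit, selected = which(Fj > crit),
                 alpha = alpha)
}

#' Martens' uncertainty test
#'
#' Jackknife significance of the PLS regression coefficients over the
#' cross-validation segments: for each venetian-blinds segment \eqn{m}
#' the coefficient vector \eqn{b^{(m)}} of the model fit without that
#' segment is recorded; the jackknife variance of \eqn{b_j} is
#' \eqn{\frac{M-1}{M} \sum_m (b_j^{(m)} - b_j)^2} against the full-data
#' coefficient \eqn{b_j}, and channel \eqn{j} is flagged when
#' \eqn{|b_j| / se_j} exceeds the two-sided t critical value at
#' \code{alpha} with the calibration model's residual degrees of freedom
#' (\eqn{n - A - 1}; the delete-group jackknife variance is computed
#' from few segments but pools all \eqn{n} samples, so the residual df,
#' not the segment count, sets the reference distribution — this keeps
#' the test near its nominal type-I level on null channels). A channel with zero
#' jackknife variance and zero coefficient is non-significant; zero
#' variance with a nonzero coefficient (identical segments) is flagged.
#'
#' @param X calibration matrix, samples x channels
#' @param y calibration response (ppm)
#' @param A component count of the tested model
#' @param s number of venetian-blind segments (default 10)
#' @param alpha significance level (default 0.05)
#' @return a \linkS4class{SelectionResult} with |t| statistics as scores
#' @export
martensSignificance <- function(X, y, A, s = 10L, alpha = 0.05) {
    X <- as.matrix(X)
    n <- nrow(X)
    folds <- venetianBlindsIndices(n, s)
    M <- max(folds)
    bFull <- fitPLS1(X, y, A)@B[, A]
    Bseg <- vapply(seq_len(M), function(m)
        fitPLS1(X[folds != m, , drop = FALSE], y[folds != m], A)@B[, A],
        numeric(ncol(X)))
    v <- (M - 1) / M * rowSums((Bseg - bFull)^2)
    se <- sqrt(v)
    tj <- ifelse(se > 0, abs(bFull) / se,
                 ifelse(bFull == 0, 0, Inf))
    crit <- stats::qt(1 - alpha / 2, df = n - A - 1)
    methods::new("SelectionResult", method = "martens", scores = tj,
                 threshold = crit, selected = which(tj > crit),
                 alpha = alpha)
}

#' Select informative channels and refit
#'
#' One-pass selection: a full-variable model is fit, channels are
#' retained by the chosen rule, and the model is refit and
#' cross-validated on the retained channels only. The returned
#' \code{predictFun} applies the mask automatically, so it accepts
#' full-width spectra.
#'
#' @param X calibration matrix, samples x channels
#' @param y calibration response (ppm)
#' @param method \code{"vip"}, \code{"smc"} or \code{"martens"}
#' @param A components of the selection model (and cap for the refit)
#' @param s venetian-blind splits for cross-validation (default 10)
#' @param threshold VIP cutoff (default 1; ignored for smc/martens)
#' @param alpha significance level for smc/martens (default 0.05)
#' @param ... passed to [crossValidate()]
#' @param selection a \linkS4class{SelectionResult} (for [nSelected()])
#' @return list with \code{selection} (\linkS4class{SelectionResult}),
#'   \code{model} (refit \linkS4class{PLSModel}), \code{cv}
#'   (\code{CVResult} on the retained channels), \code{predictFun}
#' @export
selectAndRefit <- function(X, y, method = c("vip", "smc", "martens"),
                           A, s = 10L, threshold = 1, alpha = 0.05, ...) {
    method <- match.arg(method)
    X <- as.matrix(X)
    full <- fitPLS1(X, y, A)
    sel <- switch(method,
        vip = vipSelect(full, a = A, threshold = threshold),
        smc = smcScores(full, X, y, alpha = alpha, a = A),
        martens = martensSignificance(X, y, A, s = s, alpha = alpha))
    keep <- sel@selected
    if (!length(keep))
        stop("selection retained no channels; lower the threshold or alpha")
    Xs <- X[, keep, drop = FALSE]
    Asub <- min(A, ncol(Xs))
    cv <- crossValidate(Xs, y, AMax = Asub, s = s, ...)
    model <- fitPLS1(Xs, y, Asub)
    a <- cv$chosenA
    list(selection = sel, model = model, cv = cv,
         predictFun = function(Xnew, aUse = a) {
             Xnew <- as.matrix(Xnew)
             predict(model, Xnew[, keep, drop = FALSE], a = aUse)
         })
}
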