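# Independent PLS1 oracle, coded against a different characterization of
# the model than the NIPALS implementation under test: the a-component
# PLS1 coefficient vector is the least-squares solution restricted to
# the Krylov subspace span{X'y, (X'X)X'y, ..., (X'X)^(a-1) X'y} of the
# centered data. An orthonormal Krylov basis is built by repeated
# Gram-Schmidt; no scores, loadings or deflation are involved.
krylovPLS1 <- function(X, y, A, center = TRUE) {
    X <- as.matrix(X)
    xm <- if (center) colMeans(X) else numeric(ncol(X))
    ym <- if (center) mean(y) else 0
    Xc <- sweep(X, 2, xm)
    yc <- y - ym
    G <- crossprod(Xc)               # X'X
    b <- as.numeric(crossprod(Xc, yc))
    V <- matrix(0, ncol(X), A)
    v <- b
    for (a in seq_len(A)) {
        for (rep in 1:2)             # Gram-Schmidt, twice for stability
            if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
                    crossprod(V[, 1:(a - 1), drop = FALSE], v)
        V[, a] <- v / sqrt(sum(v^2))
        v <- as.numeric(G %*% V[, a])
    }
    B <- vapply(seq_len(A), function(a) {
        Va <- V[, 1:a, drop = FALSE]
        as.numeric(Va %*% solve(crossprod(Va, G %*% Va),
                                crossprod(Va, b)))
    }, numeric(ncol(X)))
    list(B = matrix(B, ncol = A), xMean = xm, yMean = ym)
}

oraclePredict <- function(or, X, a) {
    as.numeric(or$yMean + sweep(as.matrix(X), 2, or$xMean) %*% or$B[, a])
}
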