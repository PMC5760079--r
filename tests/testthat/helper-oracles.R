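# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written against different algorithms than
# the package (ADMM instead of coordinate descent, exhaustive enumeration
# instead of closed forms) so the two routes cross-check each other.

# random symmetric positive-definite matrix with unit-scale diagonal
randomPD <- function(p, n = 4 * p) {
    X <- matrix(rnorm(n * p), n, p)
    S <- crossprod(X) / n
    (S + t(S)) / 2
}

randomPriorMatrix <- function(p, low = 0.2) {
    P <- matrix(runif(p * p, low, 1), p, p)
    P <- (P + t(P)) / 2
    diag(P) <- 0
    ids <- paste0("t", seq_len(p))
    dimnames(P) <- list(ids, ids)
    new("PriorMatrix", matrix = P,
        weights = c(default = 1, candidate = 0.5, interacting = 0.1))
}

uniformPrior <- function(p) {
    P <- matrix(1, p, p)
    diag(P) <- 0
    ids <- paste0("t", seq_len(p))
    dimnames(P) <- list(ids, ids)
    new("PriorMatrix", matrix = P,
        weights = c(default = 1, candidate = 0.5, interacting = 0.1))
}

# ADMM solver for the elementwise-penalized graphical lasso: maximizes
# logdet(Theta) - tr(Theta S) - sum(Lambda * |Theta|). Independent of the
# package's block coordinate descent.
admmGlasso <- function(S, Lambda, mu = 1, maxIter = 5000, tol = 1e-9) {
    p <- nrow(S)
    Z <- diag(1 / diag(S))
    U <- matrix(0, p, p)
    Theta <- Z
    for (it in seq_len(maxIter)) {
        eig <- eigen(mu * (Z - U) - S, symmetric = TRUE)
        d <- (eig$values + sqrt(eig$values^2 + 4 * mu)) / (2 * mu)
        Theta <- eig$vectors %*% (d * t(eig$vectors))
        Zold <- Z
        A <- Theta + U
        Z <- sign(A) * pmax(abs(A) - Lambda / mu, 0)
        U <- U + Theta - Z
        if (max(abs(Theta - Z)) < tol && max(abs(Z - Zold)) < tol) break
    }
    (Z + t(Z)) / 2
}

# KKT residual of a candidate maximizer: solve(Omega) - S must lie within
# the elementwise penalty box on zero entries and on its boundary (with the
# matching sign) on nonzero entries.
kktResidual <- function(omega, S, Lambda, zeroTol = 1e-8) {
    G <- solve(omega) - S
    up <- upper.tri(omega)
    z <- up & abs(omega) <= zeroTol
    nz <- up & abs(omega) > zeroTol
    r <- 0
    if (any(z)) r <- max(r, max(abs(G[z]) - Lambda[z]))
    if (any(nz)) r <- max(r, max(abs(G[nz] - Lambda[nz] * sign(omega[nz]))))
    r
}

# one-sided (greater) Fisher p-value by exhaustive enumeration of all
# 2x2 tables with the observed margins, using only choose()
enumFisherGreater <- function(n_i, n_j, n_ij, M) {
    r1 <- n_ij + n_i          # abstracts mentioning taxon i
    c1 <- n_ij + n_j          # abstracts mentioning taxon j
    N <- n_ij + n_i + n_j + M
    xs <- max(0, r1 + c1 - N):min(r1, c1)
    probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
    sum(probs[xs >= n_ij])
}

# brute-force AUPR: enumerate every distinct threshold, count confusion
# entries directly, integrate precision over recall with the same
# recall-0 anchor convention
bruteAupr <- function(scores, labels) {
    ths <- sort(unique(scores), decreasing = TRUE)
    rec <- prec <- numeric(0)
    for (t in ths) {
        pred <- scores >= t
        tp <- sum(pred & labels == 1)
        rec <- c(rec, tp / sum(labels == 1))
        prec <- c(prec, tp / sum(pred))
    }
    rec <- c(0, rec)
    prec <- c(prec[1], prec)
    a <- 0
    for (k in 2:length(rec))
        a <- a + (rec[k] - rec[k - 1]) * (prec[k] + prec[k - 1]) / 2
    a
}

# small OTU fixture written to a temp file; returns the path
writeOtuFixture <- function(counts, path = tempfile(fileext = ".tsv"),
                            taxaAsRows = FALSE) {
    m <- counts
    if (taxaAsRows) m <- t(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df)[1] <- if (taxaAsRows) "taxon_id" else "sample_id"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

countsFixture <- function(n = 3, p = 2, seed = 7) {
    set.seed(seed)
    m <- matrix(rpois(n * p, 20), n, p,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("otu", seq_len(p))))
    m
}

# quick synthetic dataset for end-to-end tests
quickScenario <- function(kind = "band", p = 12, n = 60, seed = 5,
                          precisionLevel = 1) {
    truth <- priorGlasso:::simulationTruth(kind, p, seed = seed)
    comp <- sampleAdditiveLogNormal(truth, n, seed = seed + 7)$composition
    prior <- syntheticPrior(truth, precisionLevel, 1, seed = seed + 13)
    list(truth = truth, comp = comp, prior = prior,
         cHat = clrCovariance(clrTransform(comp)))
}
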