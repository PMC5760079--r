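# default edge-calling threshold on |Omega_ij|
EDGE_EPS <- 1e-8

# Diagonal ridge applied when the covariance is (near-)singular, as the clr
# covariance always is (zero row sums). eps = 1e-4 * mean(diag); applied
# only when the smallest eigenvalue falls below it, so well-conditioned
# matrices are untouched.
regularizeCovariance <- function(S) {
    eps <- 1e-4 * mean(diag(S))
    if (eps <= 0) eps <- 1e-8
    evMin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (evMin < eps) S <- S + diag(eps, nrow(S))
    S
}

penalizedObjective <- function(omega, S, Lambda) {
    logDet(omega) - sum(omega * S) - sum(Lambda * abs(omega))
}

priorFor <- function(prior, p, ids = NULL) {
    if (is(prior, "PriorMatrix")) return(prior)
    if (is.null(prior)) {
        if (is.null(ids)) ids <- paste0("taxon", seq_len(p))
        return(buildPriorMatrix(ids))
    }
    stop("prior must be a PriorMatrix or NULL")
}

#' Weighted graphical lasso
#'
#' Maximizes the penalized Gaussian log-likelihood
#' `logdet(Omega) - tr(Omega C) - rho * sum_ij P_ij |Omega_ij|`
#' over symmetric positive-definite precision matrices, where the prior
#' matrix P modulates the penalty elementwise (P_ii = 0: the diagonal is
#' never penalized). Solved by block coordinate descent over columns, each
#' inner problem a weighted lasso; warm starts are used along penalty
#' paths. A singular input covariance (the clr covariance always is) gets
#' a small diagonal ridge first.
#'
#' @param cHat a [ClrCovariance-class] or symmetric covariance matrix.
#' @param prior a [PriorMatrix-class]; `NULL` means all-ones off-diagonal
#'   (plain graphical lasso).
#' @param rho non-negative penalty level.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance per sweep, relative to the mean absolute
#'   off-diagonal of `cHat`; default 1e-5.
#' @param maxIter maximum outer sweeps, default 500. Non-convergence is a
#'   warning (flagged on the result), not an error.
#' @return a [PrecisionEstimate-class].
#' @export
weightedGlasso <- function(cHat, prior = NULL, rho, tol = 1e-5,
                           maxIter = 500L) {
    S <- asCovMatrix(cHat)
    checkSquareSymmetric(S, "covariance")
    if (!is.numeric(rho) || length(rho) != 1L || rho < 0)
        stop("rho must be a non-negative scalar")
    prior <- priorFor(prior, nrow(S), rownames(S))
    P <- priorMatrix(prior)
    if (nrow(P) != nrow(S)) stop("prior and covariance dimensions differ")
    S <- regularizeCovariance(S)
    Lambda <- rho * P
    diag(Lambda) <- 0
    fit <- wglasso_cpp(S, Lambda, tol, as.integer(maxIter))
    if (!fit$converged)
        warning("weighted graphical lasso did not converge in ", maxIter,
                " sweeps")
    omega <- (fit$theta + t(fit$theta)) / 2
    dimnames(omega) <- dimnames(P)
    new("PrecisionEstimate", omega = omega, rho = rho, prior = prior,
        converged = fit$converged, nIterations = as.integer(fit$n_iter),
        objectiveValue = penalizedObjective(omega, S, Lambda))
}

# Fit the whole path (descending rho) with warm starts; internal engine
# shared by selectRho and regularizationPathScores.
fitPath <- function(S, prior, rhoDesc, tol = 1e-5, maxIter = 500L) {
    P <- priorMatrix(prior)
    S <- regularizeCovariance(S)
    fit <- wglasso_path_cpp(S, P, rhoDesc, tol, as.integer(maxIter))
    fit$S <- S
    fit
}

#' BIC of a precision estimate
#'
#' `BIC = -2 l(Omega) + |E| log(n)` with Gaussian log-likelihood
#' `l(Omega) = (n/2) (logdet(Omega) - tr(Omega C))` and `|E|` the number
#' of unordered off-diagonal nonzero pairs (threshold 1e-8).
#'
#' @param est a [PrecisionEstimate-class] (or a precision matrix).
#' @param cHat the covariance the model was fit to.
#' @param n sample size.
#' @return the BIC value.
#' @export
bicScore <- function(est, cHat, n) {
    omega <- if (is(est, "PrecisionEstimate")) precisionMatrix(est) else est
    S <- asCovMatrix(cHat)
    if (n < 2) stop("n must be at least 2")
    ll <- (n / 2) * (logDet(omega) - sum(omega * S))
    -2 * ll + networkEdgeCount(omega) * log(n)
}

#' Default penalty grid
#'
#' Log-spaced grid from `rhoMax` (the smallest penalty yielding an empty
#' graph: `max |C_ij| / P_ij` over penalized off-diagonal pairs) down to
#' `ratio * rhoMax`.
#'
#' @param cHat covariance (or [ClrCovariance-class]).
#' @param prior a [PriorMatrix-class] or `NULL`.
#' @param nRho grid size, default 30.
#' @param ratio smallest/largest penalty ratio, default 0.01.
#' @return increasing numeric vector.
#' @export
defaultRhoGrid <- function(cHat, prior = NULL, nRho = 30L, ratio = 0.01) {
    S <- asCovMatrix(cHat)
    prior <- priorFor(prior, nrow(S), rownames(S))
    P <- priorMatrix(prior)
    off <- upper.tri(S)
    pen <- off & P > 0
    rhoMax <- if (any(pen)) max(abs(S[pen]) / P[pen]) else max(abs(S[off]))
    if (!is.finite(rhoMax) || rhoMax <= 0) rhoMax <- 1
    exp(seq(log(ratio * rhoMax), log(rhoMax), length.out = nRho))
}

#' Select the penalty by BIC along a path
#'
#' Fits the weighted graphical lasso at every grid point (descending, with
#' warm starts) and returns the BIC-minimizing estimate. Ties are broken
#' toward the larger penalty (sparser model).
#'
#' @param cHat a [ClrCovariance-class] or covariance matrix.
#' @param prior a [PriorMatrix-class] or `NULL`.
#' @param rhoGrid positive penalty grid; default [defaultRhoGrid()].
#' @param n sample size (taken from `cHat` when it is a
#'   [ClrCovariance-class]).
#' @param tol,maxIter solver controls, see [weightedGlasso()].
#' @return list with elements `trace` (a [ModelSelectionTrace-class]) and
#'   `estimate` (the selected [PrecisionEstimate-class]).
#' @export
selectRho <- function(cHat, prior = NULL, rhoGrid = NULL, n = NULL,
                      tol = 1e-5, maxIter = 500L) {
    S <- asCovMatrix(cHat)
    if (is.null(n)) {
        if (!is(cHat, "ClrCovariance"))
            stop("supply n when cHat is a plain matrix")
        n <- nSamples(cHat)
    }
    prior <- priorFor(prior, nrow(S), rownames(S))
    if (is.null(rhoGrid)) rhoGrid <- defaultRhoGrid(S, prior)
    if (!length(rhoGrid)) stop("rhoGrid must be nonempty")
    if (any(rhoGrid <= 0)) stop("rhoGrid must be positive")
    rhoAsc <- sort(rhoGrid)
    rhoDesc <- rev(rhoAsc)
    fit <- fitPath(S, prior, rhoDesc, tol, maxIter)
    m <- length(rhoDesc)
    bicDesc <- numeric(m)
    edgesDesc <- integer(m)
    for (k in seq_len(m)) {
        bicDesc[k] <- bicScore(fit$thetas[[k]], S, n)
        edgesDesc[k] <- networkEdgeCount(fit$thetas[[k]])
    }
    bicAsc <- rev(bicDesc)
    edgesAsc <- rev(edgesDesc)
    # ties toward larger rho
    sel <- max(which(bicAsc <= min(bicAsc) + 1e-12))
    trace <- new("ModelSelectionTrace", rhoGrid = rhoAsc,
                 bicValues = bicAsc, edgeCounts = edgesAsc,
                 selectedIndex = as.integer(sel))
    kDesc <- m - sel + 1L
    omega <- fit$thetas[[kDesc]]
    omega <- (omega + t(omega)) / 2
    dimnames(omega) <- dimnames(priorMatrix(prior))
    Lambda <- rhoAsc[sel] * priorMatrix(prior)
    diag(Lambda) <- 0
    est <- new("PrecisionEstimate", omega = omega, rho = rhoAsc[sel],
               prior = prior, converged = fit$converged[kDesc],
               nIterations = as.integer(fit$n_iter[kDesc]),
               objectiveValue = penalizedObjective(omega, fit$S, Lambda))
    list(trace = trace, estimate = est)
}

#' Convert a precision estimate to a signed network
#'
#' Every off-diagonal entry with `|Omega_ij|` above the edge threshold
#' becomes an edge; the sign is the partial-correlation sign
#' `sign(-Omega_ij)` and the weight the partial-correlation magnitude
#' `|Omega_ij| / sqrt(Omega_ii Omega_jj)`.
#'
#' @param est a [PrecisionEstimate-class] (or precision matrix).
#' @param taxaIds node ids; defaults to the matrix dimnames.
#' @param threshold edge-calling threshold, default 1e-8.
#' @return an [AssociationNetwork-class].
#' @export
precisionToNetwork <- function(est, taxaIds = NULL, threshold = EDGE_EPS) {
    omega <- if (is(est, "PrecisionEstimate")) precisionMatrix(est) else est
    if (is.null(taxaIds)) taxaIds <- rownames(omega)
    if (is.null(taxaIds)) taxaIds <- paste0("taxon", seq_len(nrow(omega)))
    idx <- which(upper.tri(omega) & abs(omega) > threshold, arr.ind = TRUE)
    d <- sqrt(diag(omega))
    edges <- data.frame(
        taxon_i = taxaIds[idx[, 1L]],
        taxon_j = taxaIds[idx[, 2L]],
        sign = ifelse(omega[idx] < 0, 1, -1),
        weight = abs(omega[idx]) / (d[idx[, 1L]] * d[idx[, 2L]]),
        stringsAsFactors = FALSE)
    associationNetwork(edges, taxaIds)
}

#' Correlation matrix implied by a precision estimate
#'
#' Inverts the precision matrix and rescales the resulting covariance to
#' unit diagonal. Used for the L1 recovery metric, which compares
#' correlation matrices across methods.
#'
#' @param est a [PrecisionEstimate-class] (or positive-definite precision
#'   matrix).
#' @return correlation matrix with unit diagonal.
#' @export
precisionToCorrelation <- function(est) {
    omega <- if (is(est, "PrecisionEstimate")) precisionMatrix(est) else est
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("precision matrix is singular or indefinite")
    sigma <- chol2inv(chol(omega))
    stats::cov2cor(sigma)
}

#' Edge scores along the regularization path
#'
#' Scores every unordered pair by the largest penalty at which its edge is
#' still present along the path (0 if never selected). Higher scores mean
#' edges that survive stronger penalties; the ranking feeds the
#' precision-recall evaluation.
#'
#' @param cHat a [ClrCovariance-class] or covariance matrix.
#' @param prior a [PriorMatrix-class] or `NULL`.
#' @param rhoGrid penalty grid; default [defaultRhoGrid()].
#' @param tol,maxIter solver controls.
#' @return symmetric p-by-p matrix of scores (zero diagonal).
#' @export
regularizationPathScores <- function(cHat, prior = NULL, rhoGrid = NULL,
                                     tol = 1e-5, maxIter = 500L) {
    S <- asCovMatrix(cHat)
    prior <- priorFor(prior, nrow(S), rownames(S))
    if (is.null(rhoGrid)) rhoGrid <- defaultRhoGrid(S, prior)
    rhoDesc <- sort(rhoGrid, decreasing = TRUE)
    fit <- fitPath(S, prior, rhoDesc, tol, maxIter)
    pathScoresFromThetas(fit$thetas, rhoDesc, dimnames(priorMatrix(prior)))
}

pathScoresFromThetas <- function(thetas, rhoDesc, dn = NULL) {
    p <- nrow(thetas[[1L]])
    score <- matrix(0, p, p)
    for (k in seq_along(rhoDesc)) {
        sel <- abs(thetas[[k]]) > EDGE_EPS & score == 0
        diag(sel) <- FALSE
        score[sel] <- rhoDesc[k]
    }
    score <- pmax(score, t(score))
    dimnames(score) <- dn
    score
}

#' End-to-end network inference from counts
#'
#' Convenience pipeline: optional prevalence filter, optional pseudo
#' count, closure, clr transform, clr covariance, BIC-selected weighted
#' graphical lasso, network extraction.
#'
#' @param table an [OtuTable-class] or samples-by-taxa matrix.
#' @param prior a [PriorMatrix-class] or `NULL` for the uninformative
#'   prior.
#' @param pseudoCount pseudo count to add, or `NULL`/0 to skip (data must
#'   then be strictly positive).
#' @param minPrevalence prevalence filter threshold, or `NULL` to skip.
#' @param rhoGrid penalty grid; default [defaultRhoGrid()].
#' @param tol,maxIter solver controls.
#' @return list with `network` ([AssociationNetwork-class]), `estimate`
#'   ([PrecisionEstimate-class]), `trace` ([ModelSelectionTrace-class])
#'   and `cHat` ([ClrCovariance-class]).
#' @export
inferNetwork <- function(table, prior = NULL, pseudoCount = NULL,
                         minPrevalence = NULL, rhoGrid = NULL,
                         tol = 1e-5, maxIter = 500L) {
    tab <- if (is(table, "OtuTable")) table else otuTable(table)
    if (!is.null(minPrevalence)) tab <- prevalenceFilter(tab, minPrevalence)
    m <- otuCounts(tab)
    if (!is.null(pseudoCount) && pseudoCount > 0)
        m <- addPseudoCount(m, pseudoCount)
    comp <- toComposition(m)
    cHat <- clrCovariance(clrTransform(comp))
    if (!is.null(prior) &&
        !identical(taxaIds(prior), colnames(covarianceMatrix(cHat))))
        stop("prior taxa do not match the (filtered) table taxa")
    sel <- selectRho(cHat, prior, rhoGrid = rhoGrid, tol = tol,
                     maxIter = maxIter)
    list(network = precisionToNetwork(sel$estimate),
         estimate = sel$estimate, trace = sel$trace, cHat = cHat)
}
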