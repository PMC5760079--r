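test_that("weighted graphical lasso recovers the known closed-form limits", {
    # diagonal covariance: penalty forces the diagonal solution 1/C_ii
    d <- c(0.5, 1, 2, 4)
    D <- diag(d)
    dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
    for (rho in c(0.05, 0.5)) {
        fit <- weightedGlasso(D, randomPriorMatrix(4), rho)
        expect_equal(unname(precisionMatrix(fit)), diag(1 / d),
                     tolerance = 1e-8)
    }
    # rho = 0: unpenalized maximum likelihood, the plain inverse
    set.seed(2)
    S <- randomPD(6)
    fit0 <- weightedGlasso(S, NULL, 0, tol = 1e-7)
    expect_lt(max(abs(precisionMatrix(fit0) - solve(S))), 1e-4)
    expect_true(isConverged(fit0))
})

test_that("the 2x2 problem follows the soft-thresholding closed form", {
    prior <- uniformPrior(2)
    closedForm <- function(c12, lambda) {
        st <- sign(c12) * max(abs(c12) - lambda, 0)
        solve(matrix(c(1, st, st, 1), 2))
    }
    for (c12 in c(0.15, -0.3, 0.6)) {
        S <- matrix(c(1, c12, c12, 1), 2)
        dimnames(S) <- list(c("t1", "t2"), c("t1", "t2"))
        for (rho in c(0.1, 0.35, 0.7)) {
            om <- precisionMatrix(weightedGlasso(S, prior, rho, tol = 1e-8))
            expect_equal(unname(om), closedForm(c12, rho), tolerance = 1e-6)
            if (abs(c12) <= rho)    # edge shrunk exactly to zero
                expect_identical(om[1, 2], 0)
        }
    }
})

test_that("2x2 solutions maximize the objective over a dense numerical search", {
    S <- matrix(c(1, 0.4, 0.4, 1), 2,
                dimnames = list(c("t1", "t2"), c("t1", "t2")))
    rho <- 0.2
    fit <- weightedGlasso(S, uniformPrior(2), rho, tol = 1e-8)
    grid <- expand.grid(o11 = seq(0.8, 1.6, by = 0.01),
                        o22 = seq(0.8, 1.6, by = 0.01),
                        o12 = seq(-0.6, 0.2, by = 0.01))
    det2 <- grid$o11 * grid$o22 - grid$o12^2
    vals <- ifelse(grid$o11 > 0 & det2 > 1e-10,
                   log(det2) - (grid$o11 * S[1, 1] + grid$o22 * S[2, 2] +
                                2 * grid$o12 * S[1, 2]) -
                       2 * rho * abs(grid$o12),
                   -1e10)
    best <- grid[which.max(vals), ]
    om <- precisionMatrix(fit)
    expect_equal(om[1, 1], best$o11, tolerance = 0.011)
    expect_equal(om[2, 2], best$o22, tolerance = 0.011)
    expect_equal(om[1, 2], best$o12, tolerance = 0.011)
    expect_gte(objectiveValue(fit), max(vals) - 1e-6)
})

test_that("solutions satisfy the KKT conditions of the penalized likelihood", {
    set.seed(5)
    tol <- 1e-6
    for (k in 1:10) {
        p <- sample(5:20, 1)
        S <- randomPD(p)
        prior <- randomPriorMatrix(p)
        rho <- runif(1, 0.05, 0.4)
        fit <- weightedGlasso(S, prior, rho, tol = tol)
        Lambda <- rho * priorMatrix(prior)
        expect_lt(kktResidual(precisionMatrix(fit), S, Lambda), 10 * tol)
        # objective at the solution beats the diagonal start (ascent)
        diagObj <- priorGlasso:::penalizedObjective(
            diag(1 / diag(S)), S, Lambda)
        expect_gte(objectiveValue(fit), diagObj)
        # stored objective is consistent with its definition
        expect_equal(objectiveValue(fit),
                     priorGlasso:::penalizedObjective(
                         precisionMatrix(fit), S, Lambda),
                     tolerance = 1e-6)
    }
})

test_that("with a uniform prior the fit matches an independent ADMM solver", {
    set.seed(12)
    for (p in c(5, 10)) {
        S <- randomPD(p)
        rho <- 0.15
        fit <- weightedGlasso(S, uniformPrior(p), rho, tol = 1e-8)
        Lambda <- rho * (matrix(1, p, p) - diag(p))
        ref <- admmGlasso(S, Lambda)
        expect_lt(max(abs(precisionMatrix(fit) - ref)), 1e-4)
    }
})

test_that("lightening one prior entry never shrinks its precision entry", {
    set.seed(23)
    S <- randomPD(8)
    rho <- 0.25
    base <- randomPriorMatrix(8)
    omBase <- precisionMatrix(weightedGlasso(S, base, rho, tol = 1e-7))
    P2 <- priorMatrix(base)
    P2[2, 5] <- P2[5, 2] <- P2[2, 5] * 0.1
    lighter <- new("PriorMatrix", matrix = P2, weights = priorWeights(base))
    omLight <- precisionMatrix(weightedGlasso(S, lighter, rho, tol = 1e-7))
    expect_gte(abs(omLight[2, 5]) + 1e-7, abs(omBase[2, 5]))
})

test_that("BIC matches its closed form and penalizes extra edges by log(n)", {
    I2 <- diag(2)
    expect_equal(bicScore(I2, I2, n = 10), 20)
    # a negligible extra edge costs ~log(n)
    om <- diag(2); om[1, 2] <- om[2, 1] <- 1e-6
    expect_equal(bicScore(om, I2, n = 10) - bicScore(I2, I2, n = 10),
                 log(10), tolerance = 1e-3)
    # assembled-terms consistency at the diagonal (rho -> infinity) solution
    set.seed(3)
    S <- randomPD(5)
    omDiag <- diag(1 / diag(S))
    n <- 37
    byHand <- -2 * (n / 2) * (determinant(omDiag)$modulus[1] -
                              sum(omDiag * S))
    expect_equal(bicScore(omDiag, S, n), byHand, tolerance = 1e-10)
    expect_error(bicScore(matrix(c(1, 2, 2, 1), 2), I2, 10),
                 "positive definite")
})

test_that("BIC path selection is internally consistent and monotone", {
    sc <- quickScenario("band", p = 10, n = 80, seed = 31)
    grid <- defaultRhoGrid(sc$cHat, sc$prior)
    sel <- selectRho(sc$cHat, sc$prior, grid)
    tr <- sel$trace
    # edge counts trend downward in rho. Exact solution paths can bump up
    # transiently by an edge (verified against an independent ADMM solver
    # at KKT residual ~1e-11), so only larger increases are failures.
    ec <- edgeCounts(tr)
    expect_true(all(diff(ec) <= 3))
    expect_lt(cor(rhoGrid(tr), ec, method = "spearman"), -0.95)
    expect_equal(ec[length(ec)], 0L)
    # selected index minimizes the stored BIC values
    expect_equal(bicValues(tr)[tr@selectedIndex], min(bicValues(tr)))
    # the returned estimate matches the trace at the selected rho
    expect_equal(selectedRho(sel$estimate), selectedRho(tr))
    refit <- weightedGlasso(sc$cHat, sc$prior, selectedRho(tr), tol = 1e-7)
    expect_lt(max(abs(precisionMatrix(refit) -
                      precisionMatrix(sel$estimate))), 1e-3)
    # BIC recomputed independently from a refit agrees
    expect_equal(bicScore(sel$estimate, covarianceMatrix(sc$cHat),
                          nSamples(sc$cHat)),
                 bicValues(tr)[tr@selectedIndex], tolerance = 1e-8)
    # degenerate single-point grid returns that fit
    single <- selectRho(sc$cHat, sc$prior, rhoGrid = grid[15])
    expect_equal(selectedRho(single$estimate), grid[15])
    expect_error(selectRho(sc$cHat, sc$prior, rhoGrid = numeric(0)),
                 "nonempty")
})

test_that("precision estimates convert to signed networks and correlations", {
    om <- diag(3)
    dimnames(om) <- list(c("a", "b", "c"), c("a", "b", "c"))
    expect_identical(nrow(networkEdges(precisionToNetwork(om))), 0L)
    expect_equal(unname(precisionToCorrelation(om)), diag(3))

    om[1, 2] <- om[2, 1] <- -0.5
    net <- precisionToNetwork(om)
    e <- networkEdges(net)
    expect_equal(nrow(e), 1L)
    expect_equal(e$sign, 1)       # negative precision entry: positive assoc
    expect_equal(e$weight, 0.5)

    # edge count agrees with the BIC |E| on the same matrix
    expect_equal(nrow(e), priorGlasso:::networkEdgeCount(om))

    set.seed(41)
    om2 <- randomPD(6)
    R <- precisionToCorrelation(om2)
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, 6))
    expect_true(all(abs(R) <= 1 + 1e-12))
    # scaling the implied covariance back reproduces the inverse exactly
    sigma <- solve(om2)
    d <- sqrt(diag(sigma))
    expect_lt(max(abs(R * outer(d, d) - sigma)), 1e-10)
})

test_that("path scores rank edges by survival along the penalty path", {
    sc <- quickScenario("band", p = 10, n = 120, seed = 13)
    grid <- defaultRhoGrid(sc$cHat, sc$prior)
    scores <- regularizationPathScores(sc$cHat, sc$prior, grid)
    expect_equal(scores, t(scores))
    expect_true(all(scores >= 0) && max(scores) <= max(grid))
    # pairs never selected anywhere on the path score 0
    dense <- weightedGlasso(sc$cHat, sc$prior, min(grid))
    never <- abs(precisionMatrix(dense)) <= 1e-8
    diag(never) <- FALSE
    expect_true(all(scores[never] == 0))
})

test_that("path-score ranking recovers at least as many edges as magnitude ranking", {
    set.seed(19)
    hits <- matrix(NA_real_, 20, 2)
    for (r in 1:20) {
        sc <- quickScenario("random", p = 5, n = 60, seed = 100 + r)
        A <- unname(adjacencyMatrix(sc$truth))
        eTrue <- sum(A[upper.tri(A)])
        if (eTrue == 0) next
        grid <- defaultRhoGrid(sc$cHat, sc$prior)
        scores <- regularizationPathScores(sc$cHat, sc$prior, grid)
        sel <- selectRho(sc$cHat, sc$prior, grid)
        mag <- abs(precisionMatrix(sel$estimate))
        topHits <- function(s) {
            up <- which(upper.tri(s))
            top <- up[order(s[up], decreasing = TRUE)][seq_len(eTrue)]
            sum(A[top])
        }
        hits[r, ] <- c(topHits(scores), topHits(mag))
    }
    ok <- stats::complete.cases(hits)
    expect_gte(mean(hits[ok, 1]), mean(hits[ok, 2]))
})

test_that("end-to-end inference runs from counts to a network", {
    truth <- priorGlasso:::simulationTruth("band", 10, seed = 3)
    counts <- sampleNegativeBinomial(truth, 150, meanParam = 50,
                                     dispersion = 2, seed = 4)
    res <- inferNetwork(counts, pseudoCount = 0.1, minPrevalence = 0.1)
    expect_s4_class(res$network, "AssociationNetwork")
    expect_s4_class(res$estimate, "PrecisionEstimate")
    expect_true(validObject(res$trace))
    # network edge set equals the nonzero pattern of the selected estimate
    expect_equal(nrow(networkEdges(res$network)),
                 priorGlasso:::networkEdgeCount(
                     precisionMatrix(res$estimate)))
})
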