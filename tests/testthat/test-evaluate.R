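test_that("L1 distance is the mean absolute off-diagonal difference", {
    R <- diag(3)
    expect_equal(l1Distance(R, R), 0)
    a <- matrix(c(1, 0.5, 0.5, 1), 2)
    b <- matrix(c(1, 0.3, 0.3, 1), 2)
    expect_equal(l1Distance(a, b), 0.2)
    # invariant to a common relabeling of taxa
    set.seed(2)
    p <- 6
    R1 <- stats::cov2cor(randomPD(p)); R2 <- stats::cov2cor(randomPD(p))
    perm <- sample(p)
    expect_equal(l1Distance(R1, R2), l1Distance(R1[perm, perm],
                                                R2[perm, perm]))
    expect_error(l1Distance(diag(3), diag(4)), "shape")
})

test_that("edge accuracy counts pairs, not matrix entries", {
    A <- matrix(0, 4, 4)
    A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
    B <- matrix(0, 4, 4)
    B[1, 2] <- B[2, 1] <- 1; B[1, 3] <- B[3, 1] <- 1
    expect_equal(edgeAccuracy(A, A), 1)
    expect_equal(edgeAccuracy(A, B), 4 / 6)  # TP=1, TN=3 of 6 pairs
    empty <- matrix(0, 4, 4)
    expect_equal(edgeAccuracy(empty, empty), 1)
    # ACC + error fraction = 1
    set.seed(7)
    for (k in 1:10) {
        p <- sample(4:9, 1)
        mk <- function() {
            M <- matrix(stats::rbinom(p * p, 1, 0.3), p, p)
            M <- pmax(M, t(M)); diag(M) <- 0; M
        }
        t1 <- mk(); t2 <- mk()
        up <- upper.tri(t1)
        err <- sum(t1[up] != t2[up]) / (p * (p - 1) / 2)
        expect_equal(edgeAccuracy(t1, t2) + err, 1)
    }
})

test_that("AUPR handles perfect, degenerate, and hand-checked rankings", {
    A <- matrix(0, 4, 4)
    A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
    # perfect separation
    S <- matrix(0, 4, 4)
    S[1, 2] <- S[2, 1] <- 0.9; S[3, 4] <- S[4, 3] <- 0.8
    S[1, 3] <- S[3, 1] <- 0.1
    expect_equal(auprScore(S, A)$aupr, 1)
    # all-tied scores collapse to a single point at the edge density
    tied <- matrix(0.5, 4, 4); diag(tied) <- 0
    res <- auprScore(tied, A)
    expect_equal(unique(res$pr_curve$precision), 2 / 6)
    expect_equal(res$aupr, 2 / 6)
    # 6-pair toy instance against brute-force thresholding
    scores <- c(0.9, 0.8, 0.3, 0.2, 0.1, 0.05)
    labels <- c(1, 1, 0, 1, 0, 0)
    St <- matrix(0, 4, 4); At <- matrix(0, 4, 4)
    up <- which(upper.tri(St))
    St[up] <- scores; At[up] <- labels
    St <- St + t(St); At <- At + t(At)
    expect_equal(auprScore(St, At)$aupr, bruteAupr(scores, labels))
    expect_error(auprScore(St, matrix(0, 4, 4)), "no edges")
})

test_that("AUPR equals brute-force enumeration on all small instances", {
    set.seed(13)
    for (k in 1:60) {
        p <- 4                       # 6 pairs
        nPairs <- p * (p - 1) / 2
        labels <- stats::rbinom(nPairs, 1, 0.5)
        if (!sum(labels)) labels[1] <- 1
        scores <- sample(c(0, round(runif(nPairs), 2)), nPairs, TRUE)
        S <- matrix(0, p, p); A <- matrix(0, p, p)
        up <- which(upper.tri(S))
        S[up] <- scores; A[up] <- labels
        S <- S + t(S); A <- A + t(A)
        expect_equal(auprScore(S, A)$aupr, bruteAupr(scores, labels),
                     tolerance = 1e-12)
    }
})

test_that("sign accuracy follows the stated false-positive convention", {
    truth <- priorGlasso:::simulationTruth("band", 8, seed = 2)
    th <- precisionMatrix(truth)
    # estimate identical in support and sign: perfect
    expect_equal(signAccuracy(th, truth), 1)
    # single inferred edge with flipped sign: zero
    om <- diag(8)
    i <- which(adjacencyMatrix(truth) == 1 & upper.tri(th),
               arr.ind = TRUE)[1, ]
    om[i[1], i[2]] <- om[i[2], i[1]] <- -th[i[1], i[2]]
    expect_equal(signAccuracy(om, truth), 0)
    # 2 sign-correct true edges + 1 false positive: 2/3
    om <- diag(8)
    idx <- which(adjacencyMatrix(truth) == 1 & upper.tri(th), arr.ind = TRUE)
    for (r in 1:2) {
        a <- idx[r, 1]; b <- idx[r, 2]
        om[a, b] <- om[b, a] <- th[a, b]
    }
    nonEdge <- which(adjacencyMatrix(truth) == 0 & upper.tri(th),
                     arr.ind = TRUE)[1, ]
    om[nonEdge[1], nonEdge[2]] <- om[nonEdge[2], nonEdge[1]] <- 0.2
    expect_equal(signAccuracy(om, truth), 2 / 3)
    # no inferred edges: undefined
    expect_true(is.na(signAccuracy(diag(8), truth)))
    # network-based route agrees with the matrix route
    net <- precisionToNetwork(om, taxaIds = rownames(th))
    expect_equal(signAccuracy(net, truth), 2 / 3)
})

test_that("reproducibility is exactly 1 when subsampling cannot change the fit", {
    # identical samples: the clr covariance is zero for every subsample, so
    # inference always returns the same (empty) network
    comp <- matrix(rep(c(0.2, 0.3, 0.1, 0.4), each = 40), 40, 4)
    colnames(comp) <- paste0("t", 1:4)
    rownames(comp) <- paste0("s", 1:40)
    tab <- otuTable(comp)
    r <- reproducibility(tab, nRepeats = 4L, seed = 3)
    expect_equal(r$mean, 1)
    expect_equal(r$sd, 0)
    # determinism in the seed
    truth <- priorGlasso:::simulationTruth("band", 8, seed = 21)
    comp2 <- sampleAdditiveLogNormal(truth, 40, seed = 22)$composition
    tab2 <- otuTable(comp2)
    r1 <- reproducibility(tab2, nRepeats = 3L, seed = 5)
    r2 <- reproducibility(tab2, nRepeats = 3L, seed = 5)
    expect_identical(r1, r2)
    expect_true(r1$mean >= 0 && r1$mean <= 1)
})

test_that("reproducibility grows with sample size on clustered communities", {
    truth <- priorGlasso:::simulationTruth("cluster", 20, seed = 31,
        graphParams = list(groups = 2, withinProb = 0.5))
    big <- otuTable(sampleAdditiveLogNormal(truth, 400, seed = 32)$composition)
    small <- otuTable(sampleAdditiveLogNormal(truth, 40, seed = 33)$composition)
    rBig <- reproducibility(big, nRepeats = 5L, seed = 34)
    rSmall <- reproducibility(small, nRepeats = 5L, seed = 35)
    expect_gt(rBig$mean, 0.8)
    expect_gt(rBig$mean, rSmall$mean)
})

test_that("edge-set statistics behave on the documented cases", {
    e1 <- data.frame(taxon_i = c("a", "b"), taxon_j = c("b", "c"),
                     sign = 1, weight = 1)
    n1 <- associationNetwork(e1, c("a", "b", "c"))
    expect_equal(jaccardIndex(n1, n1), 1)
    e2 <- data.frame(taxon_i = "a", taxon_j = "c", sign = 1, weight = 1)
    n2 <- associationNetwork(e2, c("a", "b", "c"))
    expect_equal(jaccardIndex(n1, n2), 0)
    empty <- associationNetwork(e1[0, ], c("a", "b"))
    expect_equal(jaccardIndex(empty, empty), 1)

    expect_equal(recoveryRate(e1, n1), 1)
    expect_equal(recoveryRate(rbind(e1, e2), n1), 2 / 3)

    # rank correlation of degrees: a star compared with itself is 1 even
    # with tied leaf degrees, and a hand-built pair matches stats::cor
    star <- data.frame(taxon_i = c("a", "a", "a"),
                       taxon_j = c("b", "c", "d"), sign = 1, weight = 1)
    nStar <- associationNetwork(star, c("a", "b", "c", "d"))
    expect_equal(degreeCorrelation(nStar, nStar), 1)
    other <- data.frame(taxon_i = c("a", "a", "a", "b"),
                        taxon_j = c("b", "c", "d", "c"), sign = 1, weight = 1)
    nOther <- associationNetwork(other, c("a", "b", "c", "d"))
    expect_equal(degreeCorrelation(nStar, nOther),
                 cor(c(3, 1, 1, 1), c(3, 2, 2, 1), method = "spearman"))
    expect_error(degreeCorrelation(n1, n2, sharedTaxa = character(0)),
                 "shared")
})

test_that("metrics are invariant under consistent taxa relabeling", {
    set.seed(51)
    truth <- priorGlasso:::simulationTruth("random", 8, seed = 52)
    A <- unname(adjacencyMatrix(truth))
    S <- matrix(0, 8, 8)
    up <- which(upper.tri(S))
    S[up] <- runif(length(up)); S <- S + t(S)
    perm <- sample(8)
    expect_equal(auprScore(S, A)$aupr,
                 auprScore(S[perm, perm], A[perm, perm])$aupr)
    pred <- (S > 0.6) * 1; diag(pred) <- 0
    expect_equal(edgeAccuracy(A, pred),
                 edgeAccuracy(A[perm, perm], pred[perm, perm]))
})
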