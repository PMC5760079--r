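graphKinds <- c("random", "hub", "cluster", "band", "scale_free")

#' Generate a benchmark graph structure
#'
#' Deterministic given `seed`. Conventions per kind:
#' * `random`: each pair independently an edge with probability
#'   `prob` (default `3/p`).
#' * `hub`: disjoint stars of `hubSize` nodes (default 20, last star
#'   possibly smaller), hub connected to its leaves.
#' * `cluster`: `groups` balanced disjoint blocks (default
#'   `max(2, round(p/20))`), within-block pairs edges with probability
#'   `withinProb` (default 0.3).
#' * `band`: edge iff `0 < |i - j| <= bandwidth` (default 4).
#' * `scale_free`: preferential-attachment tree (one edge per added
#'   node), giving p - 1 edges.
#'
#' The defaults span the sparsity range of the benchmark: band(4) is the
#' densest, then cluster, then scale-free.
#'
#' @param kind one of `random`, `hub`, `cluster`, `band`, `scale_free`.
#' @param p number of taxa, at least 4.
#' @param params optional list overriding the per-kind defaults above.
#' @param seed integer seed.
#' @return binary symmetric adjacency matrix with zero diagonal and taxa
#'   dimnames.
#' @export
generateGraph <- function(kind, p, params = list(), seed = NULL) {
    if (!kind %in% graphKinds)
        stop("unknown graph kind '", kind, "'; supported: ",
             paste(graphKinds, collapse = ", "))
    if (p < 4L) stop("p must be at least 4")
    A <- matrix(0, p, p)
    withSeed(seed, {
        if (kind == "random") {
            prob <- params$prob %||% (3 / p)
            up <- upper.tri(A)
            A[up] <- as.numeric(runif(sum(up)) < prob)
        } else if (kind == "hub") {
            hubSize <- params$hubSize %||% 20L
            starts <- seq(1L, p, by = hubSize)
            for (s in starts) {
                leaves <- seq(s + 1L, min(s + hubSize - 1L, p))
                leaves <- leaves[leaves <= p & leaves > s]
                A[s, leaves] <- 1
            }
        } else if (kind == "cluster") {
            groups <- params$groups %||% max(2L, round(p / 20))
            withinProb <- params$withinProb %||% 0.3
            membership <- sort(rep_len(seq_len(groups), p))
            for (g in seq_len(groups)) {
                members <- which(membership == g)
                if (length(members) < 2L) next
                pairs <- t(utils::combn(members, 2L))
                on <- runif(nrow(pairs)) < withinProb
                A[pairs[on, , drop = FALSE]] <- 1
            }
        } else if (kind == "band") {
            bandwidth <- params$bandwidth %||% 4L
            for (k in seq_len(bandwidth)) {
                i <- seq_len(p - k)
                A[cbind(i, i + k)] <- 1
            }
        } else { # scale_free
            g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
            A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
        }
        NULL
    })
    A <- pmax(A, t(A))
    diag(A) <- 0
    dimnames(A) <- list(paste0("taxon", seq_len(p)),
                        paste0("taxon", seq_len(p)))
    A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a positive-definite precision matrix on a given support
#'
#' Off-diagonal entries for edges are drawn uniformly from
#' +/-\[`edgeValueRange`\] (sign random), the diagonal is loaded to
#' `|lambda_min| + 0.1 + u` of the off-diagonal matrix (PD margin 0.1
#' plus a conditioning constant `u`, default 0.1, the usual convention in
#' graphical-model benchmark generators), and the result is rescaled so
#' the implied covariance has unit diagonal. If the rescaling underflows an edge below
#' the support threshold the draw is repeated with a new sub-seed (with a
#' message).
#'
#' @param adjacency binary symmetric adjacency with zero diagonal.
#' @param edgeValueRange magnitude range for edge entries, default
#'   `c(0.2, 0.6)`.
#' @param u diagonal conditioning constant, default 0.1.
#' @param seed integer seed.
#' @return a [SimulationTruth-class] with `graphKind = "custom"` (use
#'   [simulationTruth()] for the labeled end-to-end constructor).
#' @export
adjacencyToPrecision <- function(adjacency, edgeValueRange = c(0.2, 0.6),
                                 u = 0.1, seed = NULL) {
    A <- adjacency
    checkSquareSymmetric(A, "adjacency", tol = 0)
    p <- nrow(A)
    ids <- rownames(A) %||% paste0("taxon", seq_len(p))
    for (attempt in 0:9) {
        theta <- withSeed(if (is.null(seed)) NULL else seed + attempt * 100003L, {
            up <- which(upper.tri(A) & A == 1)
            vals <- runif(length(up), edgeValueRange[1L], edgeValueRange[2L]) *
                sample(c(-1, 1), length(up), replace = TRUE)
            Off <- matrix(0, p, p)
            Off[up] <- vals
            Off <- Off + t(Off)
            lmin <- min(eigen(Off, symmetric = TRUE, only.values = TRUE)$values)
            Th <- Off + diag(abs(lmin) + 0.1 + u, p)
            # rescale so Sigma = solve(Th) has unit diagonal
            Sg <- chol2inv(chol(Th))
            d <- sqrt(diag(Sg))
            Th <- d * Th * rep(d, each = p)   # D Th D
            (Th + t(Th)) / 2
        })
        supp <- abs(theta) > 1e-10
        diag(supp) <- FALSE
        if (identical(unname(supp * 1), unname(A * 1))) {
            sigma <- chol2inv(chol(theta))
            sigma <- (sigma + t(sigma)) / 2
            dimnames(theta) <- dimnames(sigma) <- list(ids, ids)
            R <- stats::cov2cor(sigma)
            dimnames(A) <- list(ids, ids)
            return(new("SimulationTruth", adjacency = A, theta = theta,
                       sigma = sigma, correlation = R, graphKind = "custom",
                       params = list(edgeValueRange = edgeValueRange),
                       seed = as.integer(seed %||% NA_integer_)))
        }
        message("precision rescaling destroyed support; redrawing (attempt ",
                attempt + 1L, ")")
    }
    stop("could not build a precision matrix matching the adjacency support")
}

#' Generate a full synthetic scenario
#'
#' Graph structure plus positive-definite precision/covariance pair for
#' one simulated community.
#'
#' @param graphKind see [generateGraph()].
#' @param p number of taxa.
#' @param graphParams parameters for [generateGraph()].
#' @param edgeValueRange see [adjacencyToPrecision()].
#' @param seed integer seed driving both the graph and the entries.
#' @return a [SimulationTruth-class].
#' @export
simulationTruth <- function(graphKind, p, graphParams = list(),
                            edgeValueRange = c(0.2, 0.6), seed = NULL) {
    A <- generateGraph(graphKind, p, graphParams, seed)
    truth <- adjacencyToPrecision(A, edgeValueRange,
                                  seed = if (is.null(seed)) NULL else seed + 1L)
    truth@graphKind <- graphKind
    truth@params <- c(list(p = p, edgeValueRange = edgeValueRange),
                      graphParams)
    truth@seed <- as.integer(seed %||% NA_integer_)
    truth
}

#' Sample compositions from the additive log-normal model
#'
#' Draws latent log absolute abundances `log d ~ N(mu, Sigma)` from the
#' scenario's covariance, exponentiates, and closes each sample to sum 1.
#'
#' @param truth a [SimulationTruth-class].
#' @param n number of samples.
#' @param mu mean of the log abundances (scalar or length-p), default 0.
#' @param seed integer seed.
#' @return list with `composition` (n-by-p row-stochastic matrix) and
#'   `logAbundance` (the latent n-by-p Gaussian draws).
#' @export
sampleAdditiveLogNormal <- function(truth, n, mu = 0, seed = NULL) {
    stopifnot(is(truth, "SimulationTruth"), n >= 1)
    sigma <- covarianceMatrix(truth)
    p <- nrow(sigma)
    mu <- rep_len(mu, p)
    ch <- chol(sigma)
    logd <- withSeed(seed, {
        z <- matrix(rnorm(n * p), n, p)
        sweep(z %*% ch, 2L, mu, "+")
    })
    colnames(logd) <- rownames(sigma)
    d <- exp(logd)
    list(composition = d / rowSums(d), logAbundance = logd)
}

#' Sample zero-inflated counts from a negative-binomial copula
#'
#' Draws correlated Gaussians with the scenario's correlation matrix and
#' maps each margin through the standard normal CDF and the inverse CDF of
#' a negative binomial with mean `meanParam` and size `dispersion`
#' (normal-to-anything construction). Counts include genuine zeros, which
#' mimics the zero inflation of real OTU tables; use a pseudo count before
#' the clr transform.
#'
#' @param truth a [SimulationTruth-class].
#' @param n number of samples.
#' @param meanParam marginal mean, default 10.
#' @param dispersion NB size parameter (variance = mean + mean^2/size),
#'   default 0.5.
#' @param seed integer seed.
#' @return an [OtuTable-class] of integer counts.
#' @export
sampleNegativeBinomial <- function(truth, n, meanParam = 10,
                                   dispersion = 0.5, seed = NULL) {
    stopifnot(is(truth, "SimulationTruth"), n >= 1)
    if (meanParam <= 0 || dispersion <= 0)
        stop("meanParam and dispersion must be positive")
    R <- trueCorrelation(truth)
    p <- nrow(R)
    ch <- chol(R)
    z <- withSeed(seed, matrix(rnorm(n * p), n, p) %*% ch)
    u <- pnorm(z)
    counts <- matrix(qnbinom(u, size = dispersion, mu = meanParam), n, p)
    dimnames(counts) <- list(paste0("sample", seq_len(n)), rownames(R))
    otuTable(counts)
}

#' Benchmark configuration
#'
#' @param p,n community size and sample count.
#' @param graphKind see [generateGraph()].
#' @param distribution `additive_log_normal` (default) or
#'   `negative_binomial`.
#' @param precisionLevel fraction of true edges in the synthetic prior,
#'   default 0.5.
#' @param priorFraction prior size relative to the true edge count,
#'   default 1.
#' @param nReplicates number of independent replicates, default 100
#'   (the benchmark convention; scale down for quick runs).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param graphParams,edgeValueRange generator controls.
#' @param meanParam,dispersion negative-binomial margins.
#' @param wCandidate prior weight on prior edges, default 0.5.
#' @return a list of class `simulationConfig`.
#' @export
simulationConfig <- function(p, n, graphKind,
                             distribution = c("additive_log_normal",
                                              "negative_binomial"),
                             precisionLevel = 0.5, priorFraction = 1,
                             nReplicates = 100L, seed = 1L,
                             graphParams = list(),
                             edgeValueRange = c(0.2, 0.6),
                             meanParam = 10, dispersion = 0.5,
                             wCandidate = 0.5) {
    distribution <- match.arg(distribution)
    stopifnot(p >= 4, n >= 2, precisionLevel > 0, precisionLevel <= 1)
    structure(list(p = p, n = n, graphKind = graphKind,
                   distribution = distribution,
                   precisionLevel = precisionLevel,
                   priorFraction = priorFraction,
                   nReplicates = as.integer(nReplicates),
                   seed = as.integer(seed), graphParams = graphParams,
                   edgeValueRange = edgeValueRange, meanParam = meanParam,
                   dispersion = dispersion, wCandidate = wCandidate),
              class = "simulationConfig")
}

# one replicate of the benchmark; returns the metric row
runReplicate <- function(config, replicateSeed) {
    truth <- simulationTruth(config$graphKind, config$p,
                             config$graphParams, config$edgeValueRange,
                             seed = replicateSeed)
    if (config$distribution == "additive_log_normal") {
        comp <- sampleAdditiveLogNormal(truth, config$n,
                                        seed = replicateSeed + 7L)$composition
    } else {
        counts <- otuCounts(sampleNegativeBinomial(
            truth, config$n, config$meanParam, config$dispersion,
            seed = replicateSeed + 7L))
        comp <- toComposition(addPseudoCount(counts, 0.1))
    }
    prior <- syntheticPrior(truth, config$precisionLevel,
                            config$priorFraction,
                            seed = replicateSeed + 13L,
                            wCandidate = config$wCandidate)
    cHat <- clrCovariance(clrTransform(comp))
    S <- covarianceMatrix(cHat)
    grid <- defaultRhoGrid(S, prior)
    rhoDesc <- rev(grid)
    fit <- fitPath(S, prior, rhoDesc)
    bic <- vapply(fit$thetas, bicScore, numeric(1), cHat = S, n = config$n)
    selDesc <- min(which(bic <= min(bic) + 1e-12))  # largest rho on ties
    omega <- fit$thetas[[selDesc]]
    predAdj <- (abs(omega) > EDGE_EPS) * 1
    diag(predAdj) <- 0
    scores <- pathScoresFromThetas(fit$thetas, rhoDesc)
    trueAdj <- unname(adjacencyMatrix(truth))
    data.frame(
        replicate = NA_integer_,
        rho_selected = rhoDesc[selDesc],
        L1 = l1Distance(unname(trueCorrelation(truth)),
                        precisionToCorrelation(omega)),
        ACC = edgeAccuracy(trueAdj, predAdj),
        AUPR = auprScore(scores, trueAdj)$aupr,
        sign_acc = signAccuracy(omega, truth))
}

#' Run the synthetic benchmark
#'
#' For each replicate: generate a ground-truth scenario, sample data,
#' build a synthetic prior at the configured precision level, run the full
#' clr / weighted-graphical-lasso / BIC pipeline, and score the recovered
#' network against the truth (L1, ACC, AUPR from regularization-path
#' scores, sign accuracy). Fully reproducible from the base seed.
#'
#' @param config a [simulationConfig()].
#' @return list with `replicates` (one row per replicate) and `summary`
#'   (mean and sd per metric).
#' @export
runBenchmark <- function(config) {
    stopifnot(inherits(config, "simulationConfig"))
    rows <- vector("list", config$nReplicates)
    for (r in seq_len(config$nReplicates)) {
        rows[[r]] <- tryCatch(
            runReplicate(config, config$seed + r * 1000L),
            error = function(e) stop("replicate ", r, ": ",
                                     conditionMessage(e), call. = FALSE))
        rows[[r]]$replicate <- r
    }
    reps <- do.call(rbind, rows)
    metrics <- c("rho_selected", "L1", "ACC", "AUPR", "sign_acc")
    summary <- data.frame(
        metric = metrics,
        mean = vapply(metrics, function(m) mean(reps[[m]], na.rm = TRUE),
                      numeric(1)),
        sd = vapply(metrics, function(m) sd(reps[[m]], na.rm = TRUE),
                    numeric(1)),
        row.names = NULL)
    list(replicates = reps, summary = summary)
}
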