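#' L1 distance between correlation matrices
#'
#' Mean absolute elementwise difference over the strictly off-diagonal
#' entries of the true and estimated correlation matrices. The elementwise
#' average (rather than a sum or operator norm) keeps the metric on the
#' 0-1 correlation scale.
#'
#' @param rTrue,rHat symmetric correlation matrices of equal shape.
#' @return non-negative scalar.
#' @export
l1Distance <- function(rTrue, rHat) {
    if (!all(dim(rTrue) == dim(rHat))) stop("matrices must have equal shape")
    off <- upper.tri(rTrue) | lower.tri(rTrue)
    mean(abs(rTrue[off] - rHat[off]))
}

binaryAdjacencyCheck <- function(A, name) {
    checkSquareSymmetric(A, name, tol = 0)
    if (!all(A %in% c(0, 1))) stop(name, " must be binary")
    if (any(diag(A) != 0)) stop(name, " must have zero diagonal")
    invisible(A)
}

#' Edge recovery accuracy
#'
#' `(TP + TN) / (p (p - 1) / 2)`: the fraction of unordered taxon pairs
#' whose edge/non-edge status is predicted correctly.
#'
#' @param trueAdj,predAdj binary symmetric adjacency matrices with zero
#'   diagonal.
#' @return accuracy in \[0, 1\].
#' @export
edgeAccuracy <- function(trueAdj, predAdj) {
    if (!all(dim(trueAdj) == dim(predAdj)))
        stop("matrices must have equal shape")
    binaryAdjacencyCheck(trueAdj, "trueAdj")
    binaryAdjacencyCheck(predAdj, "predAdj")
    up <- upper.tri(trueAdj)
    mean(trueAdj[up] == predAdj[up])
}

#' Area under the precision-recall curve for edge recovery
#'
#' Ranks all unordered pairs by score (sign-blind), sweeps a descending
#' threshold over the unique score values (ties processed as one group),
#' records (recall, precision) at each, and integrates precision over
#' recall by the trapezoidal rule, anchoring the curve at recall 0 with
#' the first finite precision.
#'
#' @param scores symmetric p-by-p score matrix (e.g. from
#'   [regularizationPathScores()]); pairs without a score count as 0.
#' @param trueAdj binary symmetric adjacency with at least one edge.
#' @return list with `aupr` and `pr_curve` (data.frame of recall,
#'   precision with non-decreasing recall).
#' @export
auprScore <- function(scores, trueAdj) {
    binaryAdjacencyCheck(trueAdj, "trueAdj")
    if (!all(dim(scores) == dim(trueAdj)))
        stop("matrices must have equal shape")
    up <- upper.tri(trueAdj)
    s <- scores[up]
    y <- trueAdj[up]
    nPos <- sum(y)
    if (nPos == 0) stop("truth has no edges; AUPR undefined")
    thresholds <- sort(unique(s), decreasing = TRUE)
    recall <- precision <- numeric(length(thresholds))
    for (k in seq_along(thresholds)) {
        sel <- s >= thresholds[k]
        tp <- sum(y[sel])
        recall[k] <- tp / nPos
        precision[k] <- tp / sum(sel)
    }
    curve <- data.frame(recall = c(0, recall),
                        precision = c(precision[1L], precision))
    aupr <- sum(diff(curve$recall) *
                (utils::head(curve$precision, -1) +
                 utils::tail(curve$precision, -1)) / 2)
    list(aupr = aupr, pr_curve = curve)
}

#' Sign recovery accuracy
#'
#' The fraction of inferred edges whose sign matches the true association
#' sign. Signs are partial-correlation signs: `sign(-Omega_ij)` for the
#' estimate, `sign(-Theta_ij)` for the truth. Inferred edges absent from
#' the true graph count as incorrect. Undefined (NA) when no edge is
#' inferred.
#'
#' @param est a [PrecisionEstimate-class], precision matrix, or
#'   [AssociationNetwork-class].
#' @param truth a [SimulationTruth-class].
#' @return fraction in \[0, 1\], or `NA` when no edges were inferred.
#' @export
signAccuracy <- function(est, truth) {
    stopifnot(is(truth, "SimulationTruth"))
    theta <- precisionMatrix(truth)
    ids <- rownames(theta)
    if (is(est, "AssociationNetwork")) {
        e <- networkEdges(est)
        if (!nrow(e)) return(NA_real_)
        i <- match(e$taxon_i, ids); j <- match(e$taxon_j, ids)
        trueSign <- sign(-theta[cbind(i, j)])
        return(mean(e$sign == trueSign &
                    adjacencyMatrix(truth)[cbind(i, j)] == 1))
    }
    omega <- if (is(est, "PrecisionEstimate")) precisionMatrix(est) else est
    up <- which(upper.tri(omega) & abs(omega) > EDGE_EPS)
    if (!length(up)) return(NA_real_)
    A <- adjacencyMatrix(truth)
    good <- A[up] == 1 & sign(-omega[up]) == sign(-theta[up])
    mean(good)
}

#' Network reproducibility under subsampling
#'
#' Infers a "gold standard" network from the full table, then repeatedly
#' re-infers from random half subsamples (without replacement) and scores
#' the agreement with the gold standard. Agreement counts all
#' `p (p - 1) / 2` pairs, edges and non-edges alike
#' (`agreement = "all_pairs"`, the default); `"edges_only"` restricts to
#' the gold-standard edge set (Jaccard-style recall of gold edges).
#'
#' @param table an [OtuTable-class].
#' @param prior a [PriorMatrix-class] or `NULL`.
#' @param nRepeats number of subsamples, default 20.
#' @param subsampleFraction fraction of samples kept, default 0.5.
#' @param seed integer seed.
#' @param pseudoCount pseudo count for zero-containing data, `NULL` to
#'   skip.
#' @param agreement `"all_pairs"` or `"edges_only"`.
#' @param ... passed to [inferNetwork()].
#' @return list with `mean`, `sd` and the per-repeat `values`.
#' @export
reproducibility <- function(table, prior = NULL, nRepeats = 20L,
                            subsampleFraction = 0.5, seed = NULL,
                            pseudoCount = NULL,
                            agreement = c("all_pairs", "edges_only"), ...) {
    agreement <- match.arg(agreement)
    stopifnot(is(table, "OtuTable"))
    n <- nSamples(table)
    if (n < 4L) stop("need at least 4 samples")
    gold <- inferNetwork(table, prior, pseudoCount = pseudoCount, ...)
    goldAdj <- adjacencyMatrix(gold$network)
    up <- upper.tri(goldAdj)
    m <- otuCounts(table)
    values <- withSeed(seed, {
        vapply(seq_len(nRepeats), function(r) {
            keep <- sample.int(n, floor(n * subsampleFraction))
            sub <- inferNetwork(otuTable(m[keep, , drop = FALSE]), prior,
                                pseudoCount = pseudoCount, ...)
            subAdj <- adjacencyMatrix(sub$network)
            if (agreement == "all_pairs")
                mean(goldAdj[up] == subAdj[up])
            else {
                edges <- up & goldAdj == 1
                if (!any(edges)) return(1)
                mean(subAdj[edges] == 1)
            }
        }, numeric(1))
    })
    list(mean = mean(values), sd = sd(values), values = values)
}

edgeKeySet <- function(x) {
    if (is(x, "AssociationNetwork")) {
        e <- networkEdges(x)
        return(pairKey(e$taxon_i, e$taxon_j))
    }
    if (is.data.frame(x)) return(pairKey(x$taxon_i, x$taxon_j))
    as.character(x)
}

#' Jaccard index of two edge sets
#'
#' @param edgesA,edgesB [AssociationNetwork-class] objects, edge
#'   data.frames, or character vectors of pair keys.
#' @return `|A intersect B| / |A union B|`; 1 when both sets are empty.
#' @export
jaccardIndex <- function(edgesA, edgesB) {
    a <- unique(edgeKeySet(edgesA))
    b <- unique(edgeKeySet(edgesB))
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
}

#' Recovery rate of candidate associated pairs
#'
#' The fraction of literature-supported candidate pairs that appear among
#' the inferred edges.
#'
#' @param candidatePairs data.frame with `taxon_i`, `taxon_j` (e.g. the
#'   significant rows of [fisherScreen()]), or a character vector of pair
#'   keys.
#' @param inferredEdges an [AssociationNetwork-class] or edge data.frame.
#' @return fraction in \[0, 1\].
#' @export
recoveryRate <- function(candidatePairs, inferredEdges) {
    cand <- unique(edgeKeySet(candidatePairs))
    if (!length(cand)) stop("no candidate pairs supplied")
    inferred <- edgeKeySet(inferredEdges)
    mean(cand %in% inferred)
}

#' Spearman correlation of node degrees across two networks
#'
#' @param netA,netB [AssociationNetwork-class] objects.
#' @param sharedTaxa taxa to compare on; defaults to the intersection of
#'   the two node sets.
#' @return Spearman rank correlation of the degree sequences.
#' @export
degreeCorrelation <- function(netA, netB, sharedTaxa = NULL) {
    if (is.null(sharedTaxa))
        sharedTaxa <- intersect(taxaIds(netA), taxaIds(netB))
    if (!length(sharedTaxa)) stop("no shared taxa")
    deg <- function(net) {
        e <- networkEdges(net)
        d <- table(factor(c(e$taxon_i, e$taxon_j), levels = sharedTaxa))
        as.numeric(d)
    }
    cor(deg(netA), deg(netB), method = "spearman")
}
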