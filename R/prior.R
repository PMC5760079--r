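#' Fisher's exact test for literature co-occurrence
#'
#' Given the four abstract counts for a taxon pair — `n_ij` abstracts
#' mentioning both taxa, `n_i` only taxon i, `n_j` only taxon j, `M`
#' neither — tests whether the two taxa co-appear in abstracts more often
#' than the margins predict, via a one-sided (greater) Fisher exact test
#' on the 2-by-2 table `[[n_ij, n_i], [n_j, M]]`. The default sidedness
#' asks specifically for co-occurrence above chance; `alternative`
#' exposes the two-sided variant.
#'
#' @param n_i,n_j,n_ij,M non-negative integer abstract counts.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return the p-value.
#' @export
fisherCooccurrencePvalue <- function(n_i, n_j, n_ij, M,
                                     alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    cells <- c(n_ij, n_i, n_j, M)
    if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
        stop("abstract counts must be non-negative integers")
    if (sum(cells) == 0) stop("all four counts are zero; test undefined")
    tab <- matrix(c(n_ij, n_j, n_i, M), nrow = 2)
    fisher.test(tab, alternative = alternative)$p.value
}

#' Bonferroni correction
#'
#' @param rawP vector of p-values.
#' @param m number of tests; defaults to `length(rawP)`. For a full screen
#'   of p taxa this is `p * (p - 1) / 2`.
#' @return `pmin(1, m * rawP)`.
#' @export
bonferroniAdjust <- function(rawP, m = length(rawP)) {
    if (!is.numeric(m) || length(m) != 1L || m <= 0)
        stop("m must be a positive number of tests")
    if (m < length(rawP)) stop("m must be at least the number of p-values")
    if (any(rawP < 0 | rawP > 1)) stop("p-values must lie in [0, 1]")
    pmin(1, m * rawP)
}

#' Flag pairs with no literature co-occurrence signal
#'
#' A pair whose Bonferroni-adjusted co-occurrence p-value is not below
#' `alpha` shows no evidence of appearing together above chance; such
#' pairs keep the full (default) penalty. The decision is strict:
#' significance requires `adjustedP < alpha`.
#'
#' @param adjustedP adjusted p-value(s) in \[0, 1\].
#' @param alpha significance level, default 0.001.
#' @return logical: `TRUE` = non-associated (full penalty).
#' @export
classifyNonAssociated <- function(adjustedP, alpha = 0.001) {
    if (any(adjustedP < 0 | adjustedP > 1)) stop("p-values must lie in [0, 1]")
    !(adjustedP < alpha)
}

#' Run the co-occurrence screen on a counts table
#'
#' Computes the one-sided Fisher p-value for every pair in a co-occurrence
#' counts data.frame, applies Bonferroni correction and the significance
#' rule.
#'
#' @param counts data.frame from [readCooccurrenceCounts()].
#' @param alpha significance level, default 0.001.
#' @param m number of tests for the correction; defaults to the number of
#'   rows (pairs actually tested).
#' @return the input data.frame with columns `raw_p`, `adjusted_p` and
#'   `non_associated` appended.
#' @export
fisherScreen <- function(counts, alpha = 0.001, m = nrow(counts)) {
    raw <- mapply(fisherCooccurrencePvalue,
                  counts$n_i, counts$n_j, counts$n_ij, counts$M)
    counts$raw_p <- as.numeric(raw)
    counts$adjusted_p <- bonferroniAdjust(counts$raw_p, m)
    counts$non_associated <- classifyNonAssociated(counts$adjusted_p, alpha)
    counts
}

#' Assemble the elementwise penalty matrix
#'
#' Entry (i, j) of the prior matrix P scales the L1 penalty on the
#' corresponding precision entry. Pairs with a curated `interacting` label
#' get the lightest penalty `wInteracting` — labels take precedence over
#' (and override) the Fisher screen. Otherwise, pairs the screen found
#' significantly co-occurring get `wCandidate`; everything else (screened
#' non-associated, untested, `non_interacting` or `unknown` labels)
#' keeps the full weight `wDefault`. With no evidence at all the result is
#' an all-ones off-diagonal matrix and the estimator reduces to the plain
#' graphical lasso.
#'
#' @param taxaIds character vector of the p taxa.
#' @param fisher optional data.frame from [fisherScreen()] (columns
#'   `taxon_i`, `taxon_j`, `non_associated`).
#' @param labels optional data.frame from [readInteractionLabels()].
#' @param wDefault,wCandidate,wInteracting weights in \[0, 1\], defaults
#'   1, 0.5, 0.1.
#' @return a [PriorMatrix-class].
#' @export
buildPriorMatrix <- function(taxaIds, fisher = NULL, labels = NULL,
                             wDefault = 1, wCandidate = 0.5,
                             wInteracting = 0.1) {
    w <- c(default = wDefault, candidate = wCandidate,
           interacting = wInteracting)
    if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
    p <- length(taxaIds)
    P <- matrix(wDefault, p, p, dimnames = list(taxaIds, taxaIds))
    setPair <- function(i, j, value) {
        P[cbind(i, j)] <<- value
        P[cbind(j, i)] <<- value
    }
    if (!is.null(fisher) && nrow(fisher)) {
        unknown <- setdiff(c(fisher$taxon_i, fisher$taxon_j), taxaIds)
        if (length(unknown))
            stop("fisher results name taxa outside taxaIds: ",
                 paste(unknown, collapse = ", "))
        cand <- fisher[!fisher$non_associated, , drop = FALSE]
        if (nrow(cand)) setPair(cand$taxon_i, cand$taxon_j, wCandidate)
    }
    if (!is.null(labels) && nrow(labels)) {
        unknown <- setdiff(c(labels$taxon_i, labels$taxon_j), taxaIds)
        if (length(unknown))
            stop("labels name taxa outside taxaIds: ",
                 paste(unknown, collapse = ", "))
        inter <- labels[labels$label == "interacting", , drop = FALSE]
        if (nrow(inter)) setPair(inter$taxon_i, inter$taxon_j, wInteracting)
    }
    diag(P) <- 0
    new("PriorMatrix", matrix = P, weights = w)
}

#' Synthetic prior of controlled precision
#'
#' Builds a prior for a simulated scenario the way an imperfect literature
#' screen would: a prior edge set of size
#' `K = round(priorFraction * E_true)` containing
#' `round(precisionLevel * K)` edges drawn uniformly from the true graph
#' and the remainder drawn uniformly from non-edges. Prior edges receive
#' the `candidate` weight; all other pairs keep the default weight. A
#' precision level of 0.1 therefore means 90% of the prior edges are
#' spurious.
#'
#' @param truth a [SimulationTruth-class].
#' @param precisionLevel fraction of prior edges that are true, in (0, 1\].
#' @param priorFraction prior edge count as a fraction of the true edge
#'   count, in \[0, 1\]; default 1 (prior network as large as the truth).
#' @param seed integer seed; the construction is deterministic given it.
#' @param wDefault,wCandidate penalty weights, defaults 1 and 0.5.
#' @return a [PriorMatrix-class].
#' @export
syntheticPrior <- function(truth, precisionLevel, priorFraction = 1,
                           seed = NULL, wDefault = 1, wCandidate = 0.5) {
    stopifnot(is(truth, "SimulationTruth"))
    if (precisionLevel <= 0 || precisionLevel > 1)
        stop("precisionLevel must lie in (0, 1]")
    if (priorFraction < 0 || priorFraction > 1)
        stop("priorFraction must lie in [0, 1]")
    A <- adjacencyMatrix(truth)
    p <- nrow(A)
    ids <- rownames(A)
    if (is.null(ids)) ids <- paste0("taxon", seq_len(p))
    up <- which(upper.tri(A))
    trueEdges <- up[A[up] == 1]
    nonEdges <- up[A[up] == 0]
    eTrue <- length(trueEdges)
    if (eTrue < 1L) stop("true graph has no edges")
    K <- round(priorFraction * eTrue)
    nTrue <- min(round(precisionLevel * K), eTrue)
    nSpur <- K - nTrue
    if (nSpur > length(nonEdges))
        stop("not enough non-edges to supply ", nSpur, " spurious prior edges")
    chosen <- withSeed(seed, {
        c(trueEdges[sample.int(eTrue, nTrue)],
          nonEdges[sample.int(length(nonEdges), nSpur)])
    })
    P <- matrix(wDefault, p, p, dimnames = list(ids, ids))
    P[chosen] <- wCandidate
    P <- pmin(P, t(P))      # chosen indices are upper-triangular
    diag(P) <- 0
    new("PriorMatrix", matrix = P,
        weights = c(default = wDefault, candidate = wCandidate,
                    interacting = wCandidate))
}
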