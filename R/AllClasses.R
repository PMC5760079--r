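#' @import methods
#' @importFrom stats cov pnorm qnbinom rnorm runif setNames fisher.test
#'   p.adjust cor quantile sd
#' @importFrom utils read.delim write.table
#' @useDynLib priorGlasso, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' OTU count table
#'
#' A samples-by-taxa matrix of non-negative integer counts with unique
#' sample and taxon identifiers stored as dimnames. This is the entry point
#' of the pipeline: raw counts are pseudo-counted, closed to compositions
#' and centered-log-ratio transformed downstream.
#'
#' @slot counts numeric matrix, n samples (rows) by p taxa (columns);
#'   non-negative, with unique rownames (samples) and colnames (taxa).
#' @export
setClass("OtuTable", representation(counts = "matrix"))

setValidity("OtuTable", function(object) {
    m <- object@counts
    if (!is.numeric(m)) return("counts must be numeric")
    if (any(!is.finite(m))) return("counts must be finite")
    if (any(m < 0)) return("counts must be non-negative")
    if (ncol(m) < 2L) return("need at least 2 taxa")
    if (nrow(m) < 1L) return("need at least 1 sample")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("counts must have sample rownames and taxa colnames")
    if (anyDuplicated(rownames(m))) return("duplicate sample ids")
    if (anyDuplicated(colnames(m))) return("duplicate taxa ids")
    TRUE
})

#' Elementwise penalty (prior) matrix
#'
#' Symmetric p-by-p matrix of penalty weights in \[0, 1\] applied
#' elementwise to the graphical-lasso L1 penalty. Large entries (default 1)
#' penalize an association as in the plain graphical lasso; smaller entries
#' encode literature support: candidate co-occurrence pairs and curated
#' interacting pairs receive progressively lighter penalties. The diagonal
#' is 0 (precision diagonals are never penalized).
#'
#' @slot matrix symmetric numeric matrix with entries in \[0, 1\], zero
#'   diagonal, dimnames = taxa ids.
#' @slot weights named numeric vector with elements `default`, `candidate`
#'   and `interacting` recording the weight configuration used to build it.
#' @export
setClass("PriorMatrix",
    representation(matrix = "matrix", weights = "numeric"))

setValidity("PriorMatrix", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("prior matrix must be square")
    if (any(!is.finite(m))) return("prior entries must be finite")
    if (any(m < 0 | m > 1)) return("prior entries must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-12) return("prior matrix must be symmetric")
    if (any(diag(m) != 0)) return("prior diagonal must be 0")
    if (is.null(rownames(m))) return("prior matrix must carry taxa ids")
    TRUE
})

#' Centered log-ratio covariance
#'
#' Empirical covariance of clr-transformed compositions, the plug-in for
#' the covariance of log absolute abundances. Rows and columns sum to ~0
#' because clr rows are zero-sum, so the matrix is singular by construction.
#'
#' @slot matrix p-by-p symmetric covariance matrix with taxa dimnames.
#' @slot nSamples number of samples the estimate is based on.
#' @export
setClass("ClrCovariance",
    representation(matrix = "matrix", nSamples = "integer"))

setValidity("ClrCovariance", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("covariance must be square")
    if (max(abs(m - t(m))) > 1e-10) return("covariance must be symmetric")
    if (any(diag(m) < -1e-12)) return("covariance diagonal must be >= 0")
    if (object@nSamples < 2L) return("nSamples must be >= 2")
    TRUE
})

#' Penalized precision-matrix estimate
#'
#' The maximizer of the weighted graphical-lasso objective
#' `logdet(Omega) - tr(Omega C) - rho * sum(P * |Omega|)` at one penalty
#' level, with convergence diagnostics.
#'
#' @slot omega symmetric positive-definite p-by-p precision matrix.
#' @slot rho scalar penalty level.
#' @slot prior the [PriorMatrix-class] used.
#' @slot converged logical convergence flag.
#' @slot nIterations number of outer coordinate-descent sweeps used.
#' @slot objectiveValue penalized log-likelihood at `omega`.
#' @export
setClass("PrecisionEstimate",
    representation(omega = "matrix", rho = "numeric", prior = "PriorMatrix",
                   converged = "logical", nIterations = "integer",
                   objectiveValue = "numeric"))

setValidity("PrecisionEstimate", function(object) {
    m <- object@omega
    if (nrow(m) != ncol(m)) return("omega must be square")
    if (max(abs(m - t(m))) > 1e-8) return("omega must be symmetric")
    if (length(object@rho) != 1L || object@rho < 0)
        return("rho must be a non-negative scalar")
    TRUE
})

#' BIC model-selection trace along a penalty path
#'
#' Records, for every penalty level on the grid, the BIC score and the
#' number of inferred edges, together with the index of the selected level.
#'
#' @slot rhoGrid increasing vector of penalty levels.
#' @slot bicValues BIC per grid point.
#' @slot edgeCounts inferred edge count per grid point.
#' @slot selectedIndex index (into `rhoGrid`) minimizing BIC; ties broken
#'   toward the larger (sparser) penalty.
#' @export
setClass("ModelSelectionTrace",
    representation(rhoGrid = "numeric", bicValues = "numeric",
                   edgeCounts = "integer", selectedIndex = "integer"))

setValidity("ModelSelectionTrace", function(object) {
    if (is.unsorted(object@rhoGrid)) return("rhoGrid must be sorted")
    if (any(object@rhoGrid <= 0)) return("rhoGrid must be positive")
    k <- length(object@rhoGrid)
    if (length(object@bicValues) != k || length(object@edgeCounts) != k)
        return("trace vectors must share the grid length")
    i <- object@selectedIndex
    if (i < 1L || i > k) return("selectedIndex out of range")
    if (abs(object@bicValues[i] - min(object@bicValues)) > 1e-9)
        return("selectedIndex must minimize BIC")
    TRUE
})

#' Undirected signed association network
#'
#' Edge list over taxa with partial-correlation signs and magnitudes.
#' Edges are stored with `taxon_i < taxon_j` lexicographically so the
#' representation (and file output) is deterministic.
#'
#' @slot edges data.frame with columns `taxon_i`, `taxon_j` (character),
#'   `sign` (+1/-1) and `weight` (non-negative partial-correlation
#'   magnitude).
#' @slot taxaIds character vector of all node ids (isolated nodes included).
#' @export
setClass("AssociationNetwork",
    representation(edges = "data.frame", taxaIds = "character"))

setValidity("AssociationNetwork", function(object) {
    e <- object@edges
    need <- c("taxon_i", "taxon_j", "sign", "weight")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$taxon_i == e$taxon_j)) return("self-edges are not allowed")
        if (any(e$taxon_i > e$taxon_j))
            return("edges must be ordered taxon_i < taxon_j")
        if (anyDuplicated(paste(e$taxon_i, e$taxon_j)))
            return("duplicate edges")
        if (!all(e$sign %in% c(-1, 1))) return("signs must be +1/-1")
        if (any(!is.finite(e$weight))) return("weights must be finite")
        if (!all(c(e$taxon_i, e$taxon_j) %in% object@taxaIds))
            return("edge endpoints must be listed in taxaIds")
    }
    if (anyDuplicated(object@taxaIds)) return("duplicate taxa ids")
    TRUE
})

#' Ground truth of one synthetic scenario
#'
#' The generating graph and Gaussian parameters for one simulated dataset:
#' adjacency, precision matrix Theta (support exactly the adjacency),
#' covariance Sigma = inverse(Theta) with unit diagonal, and the implied
#' correlation matrix.
#'
#' @slot adjacency binary symmetric p-by-p matrix, zero diagonal.
#' @slot theta positive-definite precision matrix.
#' @slot sigma covariance, the inverse of `theta`.
#' @slot correlation correlation matrix derived from `sigma`.
#' @slot graphKind one of random, hub, cluster, band, scale_free.
#' @slot params generator parameters (list).
#' @slot seed integer seed the scenario was generated from.
#' @export
setClass("SimulationTruth",
    representation(adjacency = "matrix", theta = "matrix", sigma = "matrix",
                   correlation = "matrix", graphKind = "character",
                   params = "list", seed = "integer"))

setValidity("SimulationTruth", function(object) {
    A <- object@adjacency
    if (!all(A %in% c(0, 1))) return("adjacency must be binary")
    if (any(diag(A) != 0)) return("adjacency diagonal must be 0")
    if (max(abs(A - t(A))) > 0) return("adjacency must be symmetric")
    if (max(abs(object@sigma %*% object@theta - diag(nrow(A)))) > 1e-6)
        return("sigma must invert theta")
    supp <- abs(object@theta) > 1e-10; diag(supp) <- FALSE
    if (!identical(unname(supp * 1), unname(A * 1)))
        return("theta support must equal adjacency")
    TRUE
})

setMethod("show", "OtuTable", function(object) {
    cat(sprintf("OtuTable: %d samples x %d taxa\n",
        nrow(object@counts), ncol(object@counts)))
    cat(sprintf("  total counts: %g; zero fraction: %.3f\n",
        sum(object@counts), mean(object@counts == 0)))
})

setMethod("show", "PriorMatrix", function(object) {
    m <- object@matrix
    off <- m[upper.tri(m)]
    cat(sprintf("PriorMatrix: %d taxa; %d off-diagonal pairs below default weight\n",
        nrow(m), sum(off < max(off, 1))))
    cat("  weights:", paste(names(object@weights), object@weights,
        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PrecisionEstimate", function(object) {
    cat(sprintf("PrecisionEstimate: p=%d, rho=%.4g, edges=%d, %s (%d sweeps)\n",
        nrow(object@omega), object@rho, networkEdgeCount(object@omega),
        if (object@converged) "converged" else "NOT converged",
        object@nIterations))
})

setMethod("show", "ModelSelectionTrace", function(object) {
    cat(sprintf("ModelSelectionTrace: %d penalty levels in [%.4g, %.4g]\n",
        length(object@rhoGrid), min(object@rhoGrid), max(object@rhoGrid)))
    cat(sprintf("  selected rho=%.4g with %d edges (BIC %.2f)\n",
        object@rhoGrid[object@selectedIndex],
        object@edgeCounts[object@selectedIndex],
        object@bicValues[object@selectedIndex]))
})

setMethod("show", "AssociationNetwork", function(object) {
    cat(sprintf("AssociationNetwork: %d taxa, %d edges (%d positive)\n",
        length(object@taxaIds), nrow(object@edges),
        sum(object@edges$sign > 0)))
})

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf("SimulationTruth: %s graph, p=%d, %d edges (seed %d)\n",
        object@graphKind, nrow(object@adjacency),
        sum(object@adjacency) / 2, object@seed))
})
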