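#' Accessors for the core classes
#'
#' Slot access goes through these functions; the slot layout is not part of
#' the API.
#'
#' @param object an object of the documented class.
#' @return `otuCounts`: the samples-by-taxa count matrix. `taxaIds`,
#'   `sampleIds`: character vectors of identifiers. `priorWeights`: the
#'   named weight configuration. `precisionMatrix`, `covarianceMatrix`,
#'   `adjacencyMatrix`, `trueCorrelation`: the respective matrices.
#'   `networkEdges`: the edge data.frame. `selectedRho`: the BIC-selected
#'   penalty.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(object) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setMethod("otuCounts", "OtuTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("taxaIds", function(object) standardGeneric("taxaIds"))
#' @rdname accessors
#' @export
setMethod("taxaIds", "OtuTable", function(object) colnames(object@counts))
#' @rdname accessors
#' @export
setMethod("taxaIds", "PriorMatrix", function(object) rownames(object@matrix))
#' @rdname accessors
#' @export
setMethod("taxaIds", "AssociationNetwork", function(object) object@taxaIds)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "OtuTable", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setGeneric("priorMatrix", function(object) standardGeneric("priorMatrix"))
#' @rdname accessors
#' @export
setMethod("priorMatrix", "PriorMatrix", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("priorMatrix", "PrecisionEstimate", function(object) object@prior)

#' @rdname accessors
#' @export
setGeneric("priorWeights", function(object) standardGeneric("priorWeights"))
#' @rdname accessors
#' @export
setMethod("priorWeights", "PriorMatrix", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("precisionMatrix", function(object) standardGeneric("precisionMatrix"))
#' @rdname accessors
#' @export
setMethod("precisionMatrix", "PrecisionEstimate", function(object) object@omega)
#' @rdname accessors
#' @export
setMethod("precisionMatrix", "SimulationTruth", function(object) object@theta)

#' @rdname accessors
#' @export
setGeneric("covarianceMatrix", function(object) standardGeneric("covarianceMatrix"))
#' @rdname accessors
#' @export
setMethod("covarianceMatrix", "ClrCovariance", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("covarianceMatrix", "SimulationTruth", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "ClrCovariance", function(object) object@nSamples)
#' @rdname accessors
#' @export
setMethod("nSamples", "OtuTable", function(object) nrow(object@counts))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "SimulationTruth", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "AssociationNetwork", function(object) {
    p <- length(object@taxaIds)
    A <- matrix(0, p, p, dimnames = list(object@taxaIds, object@taxaIds))
    e <- object@edges
    if (nrow(e)) {
        A[cbind(e$taxon_i, e$taxon_j)] <- 1
        A[cbind(e$taxon_j, e$taxon_i)] <- 1
    }
    A
})

#' @rdname accessors
#' @export
setGeneric("trueCorrelation", function(object) standardGeneric("trueCorrelation"))
#' @rdname accessors
#' @export
setMethod("trueCorrelation", "SimulationTruth", function(object) object@correlation)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "AssociationNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "PrecisionEstimate", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setMethod("objectiveValue", "PrecisionEstimate", function(object) object@objectiveValue)

#' @rdname accessors
#' @export
setGeneric("selectedRho", function(object) standardGeneric("selectedRho"))
#' @rdname accessors
#' @export
setMethod("selectedRho", "ModelSelectionTrace", function(object)
    object@rhoGrid[object@selectedIndex])
#' @rdname accessors
#' @export
setMethod("selectedRho", "PrecisionEstimate", function(object) object@rho)

#' @rdname accessors
#' @export
setGeneric("rhoGrid", function(object) standardGeneric("rhoGrid"))
#' @rdname accessors
#' @export
setMethod("rhoGrid", "ModelSelectionTrace", function(object) object@rhoGrid)

#' @rdname accessors
#' @export
setGeneric("bicValues", function(object) standardGeneric("bicValues"))
#' @rdname accessors
#' @export
setMethod("bicValues", "ModelSelectionTrace", function(object) object@bicValues)

#' @rdname accessors
#' @export
setGeneric("edgeCounts", function(object) standardGeneric("edgeCounts"))
#' @rdname accessors
#' @export
setMethod("edgeCounts", "ModelSelectionTrace", function(object) object@edgeCounts)
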