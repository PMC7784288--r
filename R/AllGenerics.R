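#' Accessors for scBatchAlign classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @param object an object of one of the package's S4 classes (show methods).
#' @param ... further arguments (unused).
#' @return The requested component; see the individual class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("snnAdjacency", function(x, ...) standardGeneric("snnAdjacency"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, ...) {
    standardGeneric("consensusMatrix")
})

#' @rdname accessors
#' @export
setGeneric("confidentCellsOf", function(x, ...) {
    standardGeneric("confidentCellsOf")
})

#' @rdname accessors
#' @export
setGeneric("sharedPairs", function(x, ...) standardGeneric("sharedPairs"))

#' @rdname accessors
#' @export
setGeneric("pairEdges", function(x, ...) standardGeneric("pairEdges"))

#' @rdname accessors
#' @export
setGeneric("correctionVectors", function(x, ...) {
    standardGeneric("correctionVectors")
})

#' @rdname accessors
#' @export
setGeneric("technicalRatioOf", function(x, ...) {
    standardGeneric("technicalRatioOf")
})

#' @rdname accessors
#' @export
setGeneric("cellEmbedding", function(x, ...) standardGeneric("cellEmbedding"))

#' @rdname accessors
#' @export
setGeneric("batchLabels", function(x, ...) standardGeneric("batchLabels"))

#' @rdname accessors
#' @export
setMethod("snnAdjacency", "SNNGraph", function(x, ...) x@adjacency)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusClusters", function(x, ...) {
    stats::setNames(x@labels, x@cellIds)
})

#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusClusters", function(x, ...) {
    x@consensus
})

#' @rdname accessors
#' @export
setMethod("confidentCellsOf", "ConsensusClusters", function(x, ...) {
    stats::setNames(x@confident, x@cellIds)
})

#' @rdname accessors
#' @export
setMethod("pairEdges", "SharedClusterPairs", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setMethod("sharedPairs", "SharedClusterPairs", function(x, ...) {
    x@edges[x@edges$passed, , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("correctionVectors", "CorrectionBasis", function(x, ...) x@V)

#' @rdname accessors
#' @export
setMethod("technicalRatioOf", "CorrectionBasis", function(x, ...) {
    x@technicalRatio
})

#' @rdname accessors
#' @export
setMethod("cellEmbedding", "IntegrationResult", function(x, ...) x@embedding)

#' @rdname accessors
#' @export
setMethod("batchLabels", "IntegrationResult", function(x, ...) {
    stats::setNames(x@batch, rownames(x@embedding))
})

#' @rdname accessors
#' @export
setMethod("sharedPairs", "IntegrationResult", function(x, ...) {
    sharedPairs(x@pairs)
})

#' @rdname accessors
setMethod("show", "SNNGraph", function(object) {
    cat(
        "SNNGraph with", length(object@cellIds), "cells,",
        length(object@adjacency@x) / 2, "edges (k =", object@k,
        ", PCs =", object@nPCs, ")\n"
    )
})

#' @rdname accessors
setMethod("show", "ConsensusClusters", function(object) {
    cat(
        "ConsensusClusters:", length(object@cellIds), "cells in",
        object@nClusters, "clusters;",
        sum(object@confident), "confident cells\n"
    )
})

#' @rdname accessors
setMethod("show", "SharedClusterPairs", function(object) {
    cat(
        "SharedClusterPairs:", nrow(object@edges), "cluster pairs scored,",
        sum(object@edges$passed), "shared (similarity >",
        object@threshold, ")\n"
    )
})

#' @rdname accessors
setMethod("show", "CorrectionBasis", function(object) {
    cat(
        "CorrectionBasis:", ncol(object@V), "correction vectors over",
        nrow(object@V), "features (lambda =", object@lambda,
        "); technical-variation ratio",
        format(object@technicalRatio, digits = 3), "\n"
    )
})

#' @rdname accessors
setMethod("show", "IntegrationResult", function(object) {
    cat(
        "IntegrationResult:", nrow(object@embedding), "cells from",
        length(unique(object@batch)), "batches embedded in",
        ncol(object@embedding), "dimensions\n"
    )
    cat(
        "  shared cluster pairs:", sum(object@pairs@edges$passed),
        "; technical-variation ratio",
        format(object@basis@technicalRatio, digits = 3), "\n"
    )
})
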