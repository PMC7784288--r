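#' @import methods
#' @importClassesFrom Matrix Matrix
NULL

#' Shared nearest neighbor graph of cells
#'
#' Holds the weighted SNN graph built from a low-dimensional representation of
#' one dataset. Edge weights are the fraction of shared k-nearest neighbors
#' between two cells, stored as a symmetric sparse adjacency matrix with zero
#' diagonal.
#'
#' @slot adjacency symmetric sparse \code{Matrix} of SNN weights in [0, 1].
#' @slot k integer, number of nearest neighbors used.
#' @slot nPCs integer, number of principal components the kNN search used.
#' @slot cellIds character vector of cell identifiers.
#'
#' @exportClass SNNGraph
setClass("SNNGraph",
    representation(
        adjacency = "Matrix",
        k = "integer",
        nPCs = "integer",
        cellIds = "character"
    )
)

setValidity("SNNGraph", function(object) {
    a <- object@adjacency
    if (nrow(a) != ncol(a)) {
        return("adjacency must be square")
    }
    if (nrow(a) != length(object@cellIds)) {
        return("cellIds length must match adjacency dimension")
    }
    if (any(Matrix::diag(a) != 0)) {
        return("adjacency must have zero diagonal (no self-loops)")
    }
    w <- a@x
    if (length(w) && (min(w) < 0 || max(w) > 1 + 1e-12)) {
        return("SNN weights must lie in [0, 1]")
    }
    if (!Matrix::isSymmetric(a, tol = 1e-10)) {
        return("adjacency must be symmetric")
    }
    TRUE
})

#' Consensus clustering of one dataset
#'
#' Result of consensus Leiden clustering: per-cell labels from cutting an
#' average-linkage dendrogram of the consensus co-clustering matrix, the
#' consensus matrix itself, and the confident-cell annotation derived from
#' average within-cluster SNN similarity.
#'
#' @slot labels integer cluster label per cell (1..nClusters).
#' @slot consensus symmetric matrix of co-clustering frequencies across the
#'   resolution grid; entries are multiples of 1/(number of resolutions).
#' @slot nClusters integer, estimated number of clusters.
#' @slot confident logical per cell, whether it is a confident cell.
#' @slot avgSimilarity numeric per cell, mean SNN weight to its cluster mates.
#' @slot cellIds character vector of cell identifiers.
#'
#' @exportClass ConsensusClusters
setClass("ConsensusClusters",
    representation(
        labels = "integer",
        consensus = "matrix",
        nClusters = "integer",
        confident = "logical",
        avgSimilarity = "numeric",
        cellIds = "character"
    )
)

setValidity("ConsensusClusters", function(object) {
    n <- length(object@cellIds)
    if (length(object@labels) != n) {
        return("labels length must match cellIds")
    }
    if (length(object@confident) && length(object@confident) != n) {
        return("confident length must match cellIds")
    }
    if (length(object@avgSimilarity) && length(object@avgSimilarity) != n) {
        return("avgSimilarity length must match cellIds")
    }
    if (nrow(object@consensus) && (nrow(object@consensus) != n ||
        ncol(object@consensus) != n)) {
        return("consensus matrix must be n x n")
    }
    if (any(object@labels < 1L) || any(object@labels > object@nClusters)) {
        return("labels must lie in 1..nClusters")
    }
    TRUE
})

#' Shared cell clusters across datasets
#'
#' Weighted complete bipartite cluster graph for every pair of datasets:
#' one row per cluster pair with its marker-overlap score, cosine similarity
#' of mean marker expression, the combined similarity, and whether the pair
#' passes the sharing threshold.
#'
#' @slot edges data.frame with columns dataset_i, cluster_p, dataset_j,
#'   cluster_q, overlap, cosine, similarity, passed.
#' @slot threshold numeric similarity threshold T; pairs require
#'   similarity > threshold (strict).
#'
#' @exportClass SharedClusterPairs
setClass("SharedClusterPairs",
    representation(
        edges = "data.frame",
        threshold = "numeric"
    )
)

setValidity("SharedClusterPairs", function(object) {
    need <- c(
        "dataset_i", "cluster_p", "dataset_j", "cluster_q",
        "overlap", "cosine", "similarity", "passed"
    )
    if (!all(need %in% colnames(object@edges))) {
        return(paste(
            "edges must contain columns:",
            paste(need, collapse = ", ")
        ))
    }
    s <- object@edges$similarity
    if (length(s) && (min(s) < -1e-12 || max(s) > 1 + 1e-12)) {
        return("similarities must lie in [0, 1]")
    }
    if (object@threshold <= 0 || object@threshold >= 1) {
        return("threshold must lie in (0, 1)")
    }
    TRUE
})

#' Correction vectors learned from the penalized eigenproblem
#'
#' The orthonormal correction vectors V (features x k), their eigenvalues,
#' the penalty used, the column-centering vector applied to the confident-cell
#' matrix, and the technical-variation ratio. Projection of any dataset on the
#' same feature set (columns centered with \code{center}) onto V gives the
#' shared embedding.
#'
#' @slot V numeric matrix, features x k, orthonormal columns.
#' @slot eigenvalues numeric, strictly positive, descending.
#' @slot lambda numeric penalty on the technical-variation term.
#' @slot center numeric centering vector (one value per feature).
#' @slot featureIds character, row names of V.
#' @slot technicalRatio numeric in [0, 1], share of technical variation among
#'   the total variation captured by V.
#'
#' @exportClass CorrectionBasis
setClass("CorrectionBasis",
    representation(
        V = "matrix",
        eigenvalues = "numeric",
        lambda = "numeric",
        center = "numeric",
        featureIds = "character",
        technicalRatio = "numeric"
    )
)

setValidity("CorrectionBasis", function(object) {
    if (nrow(object@V) != length(object@featureIds)) {
        return("V must have one row per feature id")
    }
    if (ncol(object@V) != length(object@eigenvalues)) {
        return("one eigenvalue per correction vector required")
    }
    if (length(object@center) != nrow(object@V)) {
        return("center must have one entry per feature")
    }
    if (any(object@eigenvalues <= 0)) {
        return("eigenvalues must be strictly positive")
    }
    if (is.unsorted(rev(object@eigenvalues))) {
        return("eigenvalues must be in descending order")
    }
    if (object@lambda < 0) {
        return("lambda must be nonnegative")
    }
    cp <- crossprod(object@V)
    if (max(abs(cp - diag(ncol(object@V)))) > 1e-6) {
        return("columns of V must be orthonormal")
    }
    TRUE
})

#' Result of an end-to-end integration run
#'
#' @slot embedding numeric matrix, all cells x k, the shared embedding L.
#' @slot batch character batch label per embedded cell.
#' @slot basis the \linkS4class{CorrectionBasis} used for the projection.
#' @slot clusters named list of \linkS4class{ConsensusClusters}, one per
#'   dataset.
#' @slot pairs the \linkS4class{SharedClusterPairs} used to build the
#'   confounding matrix.
#' @slot log list of run parameters and per-stage summaries.
#'
#' @exportClass IntegrationResult
setClass("IntegrationResult",
    representation(
        embedding = "matrix",
        batch = "character",
        basis = "CorrectionBasis",
        clusters = "list",
        pairs = "SharedClusterPairs",
        log = "list"
    )
)

setValidity("IntegrationResult", function(object) {
    if (nrow(object@embedding) != length(object@batch)) {
        return("one batch label per embedded cell required")
    }
    TRUE
})
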