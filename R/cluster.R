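#' Build a shared nearest neighbor graph
#'
#' Runs PCA (column-centered, unscaled) on the cells x features matrix, finds
#' each cell's k nearest neighbors by Euclidean distance in PC space, and
#' weights each cell pair by the fraction of shared nearest neighbors,
#' |NN(i) intersect NN(j)| / k. Pairs sharing no neighbors carry no edge.
#'
#' @param fm cells x features numeric matrix (log-normalized, HVG-restricted),
#'   with cell ids as row names.
#' @param k number of nearest neighbors (default 20).
#' @param nPCs number of principal components for the kNN search (default 40;
#'   capped at min(cells, features) - 1).
#' @param jaccard if TRUE, weight edges by |NN(i) intersect NN(j)| /
#'   |NN(i) union NN(j)| instead of the default shared fraction over k.
#' @return An \linkS4class{SNNGraph}.
#' @export
buildSNN <- function(fm, k = 20L, nPCs = 40L, jaccard = FALSE) {
    fm <- as.matrix(fm)
    n <- nrow(fm)
    if (n < k + 1L) {
        stop("need at least k + 1 cells to build an SNN graph")
    }
    if (is.null(rownames(fm))) {
        rownames(fm) <- paste0("cell", seq_len(n))
    }
    nPCs <- min(nPCs, n - 1L, ncol(fm))
    pcs <- stats::prcomp(fm, center = TRUE, scale. = FALSE, rank. = nPCs)$x
    nn <- .knnIndices(pcs, k)
    # membership matrix: M[i, j] = 1 if j is among i's k nearest neighbors
    memb <- Matrix::sparseMatrix(
        i = rep(seq_len(n), each = k),
        j = as.integer(t(nn)),
        x = 1,
        dims = c(n, n)
    )
    shared <- Matrix::tcrossprod(memb) # |NN(i) intersect NN(j)|
    Matrix::diag(shared) <- 0
    shared <- Matrix::drop0(shared)
    if (jaccard) {
        # |union| = 2k - |intersect| for equal-size neighbor sets
        shared@x <- shared@x / (2 * k - shared@x)
    } else {
        shared@x <- shared@x / k
    }
    methods::new("SNNGraph",
        adjacency = methods::as(shared, "generalMatrix"),
        k = as.integer(k), nPCs = as.integer(nPCs),
        cellIds = rownames(fm)
    )
}

#' One Leiden clustering of the SNN graph
#'
#' A single run of the Leiden community detection algorithm (modularity
#' objective) on the weighted SNN graph, deterministic for a given seed.
#'
#' @param g an \linkS4class{SNNGraph}.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed making the partition reproducible.
#' @return Integer vector of cluster labels (1-based), named by cell id.
#' @export
leidenOnce <- function(g, resolution, seed = 0L) {
    stopifnot(methods::is(g, "SNNGraph"))
    ig <- igraph::graph_from_adjacency_matrix(
        g@adjacency,
        mode = "undirected", weighted = TRUE
    )
    memb <- withr::with_seed(seed, {
        igraph::membership(igraph::cluster_leiden(
            ig,
            objective_function = "modularity",
            resolution = resolution,
            n_iterations = 3L
        ))
    })
    stats::setNames(as.integer(memb), g@cellIds)
}

#' Estimate the number of clusters from a consensus matrix
#'
#' Counts the singular values of the consensus matrix whose ratio to the sum
#' of all singular values exceeds \code{ratioThreshold} (1\% by default);
#' the count is clamped to [1, n].
#'
#' @param consensus square symmetric nonnegative matrix.
#' @param ratioThreshold minimum singular-value mass fraction (default 0.01).
#' @return Integer number of clusters.
#' @export
estimateNClusters <- function(consensus, ratioThreshold = 0.01) {
    consensus <- as.matrix(consensus)
    stopifnot(nrow(consensus) == ncol(consensus))
    d <- svd(consensus, nu = 0L, nv = 0L)$d
    tot <- sum(d)
    if (tot <= 0) {
        return(1L)
    }
    k <- sum(d / tot > ratioThreshold)
    max(1L, min(as.integer(k), nrow(consensus)))
}

#' Consensus Leiden clustering of one dataset
#'
#' Clusters the SNN graph at each resolution of the grid, forms the consensus
#' matrix of co-clustering frequencies, estimates the cluster number from the
#' consensus spectrum (\code{\link{estimateNClusters}}), and cuts an
#' average-linkage dendrogram of the consensus matrix (distance = 1 -
#' consensus) into that many clusters.
#'
#' @param g an \linkS4class{SNNGraph}.
#' @param resolutions resolution grid (default 0.1 to 0.5 by 0.1).
#' @param seed master seed; per-resolution seeds are derived from it.
#' @param ratioThreshold passed to \code{\link{estimateNClusters}}.
#' @return A \linkS4class{ConsensusClusters} (confident-cell fields empty;
#'   see \code{\link{detectConfidentCells}}).
#' @export
consensusCluster <- function(g, resolutions = seq(0.1, 0.5, by = 0.1),
                             seed = 0L, ratioThreshold = 0.01) {
    stopifnot(methods::is(g, "SNNGraph"), length(resolutions) >= 1L)
    n <- length(g@cellIds)
    consensus <- matrix(0, n, n)
    for (r in seq_along(resolutions)) {
        lab <- leidenOnce(g, resolutions[r], seed = as.integer(seed) + r)
        consensus <- consensus + outer(lab, lab, "==")
    }
    consensus <- consensus / length(resolutions)
    dimnames(consensus) <- list(g@cellIds, g@cellIds)
    nClusters <- estimateNClusters(consensus, ratioThreshold)
    if (nClusters >= n) {
        labels <- seq_len(n)
    } else {
        hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
        labels <- stats::cutree(hc, k = nClusters)
    }
    methods::new("ConsensusClusters",
        labels = as.integer(labels),
        consensus = consensus,
        nClusters = as.integer(max(labels)),
        confident = logical(0),
        avgSimilarity = numeric(0),
        cellIds = g@cellIds
    )
}

#' Detect confident cells in each cluster
#'
#' For each cell, its average similarity is the mean SNN weight to all other
#' cells of its cluster (absent edges count as 0). Within each cluster the
#' confident cells are those strictly above the cluster's quantile cutoff
#' (the third quartile by default). If ties leave no cell strictly above the
#' cutoff, the top max(3, 10\% of the cluster) cells by average similarity
#' are taken instead. A singleton cluster's only cell is marked confident
#' with a warning.
#'
#' @param g the \linkS4class{SNNGraph} the clustering was computed on.
#' @param clusters a \linkS4class{ConsensusClusters}.
#' @param quantileCutoff quantile defining the cutoff (default 0.75). Raising
#'   it (e.g. to 0.9) keeps fewer confident cells and reduces the cost of the
#'   downstream eigenproblem.
#' @return The \linkS4class{ConsensusClusters} with \code{confident} and
#'   \code{avgSimilarity} filled in.
#' @export
detectConfidentCells <- function(g, clusters, quantileCutoff = 0.75) {
    stopifnot(
        methods::is(g, "SNNGraph"),
        methods::is(clusters, "ConsensusClusters"),
        quantileCutoff >= 0.5, quantileCutoff < 1
    )
    labels <- clusters@labels
    n <- length(labels)
    stopifnot(length(g@cellIds) == n)
    adj <- g@adjacency
    avg <- numeric(n)
    confident <- logical(n)
    for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        if (length(idx) == 1L) {
            warning("cluster ", cl, " is a singleton; its cell is kept as confident")
            avg[idx] <- 0
            confident[idx] <- TRUE
            next
        }
        sub <- adj[idx, idx, drop = FALSE]
        a <- Matrix::rowSums(sub) / (length(idx) - 1L)
        avg[idx] <- a
        q3 <- stats::quantile(a, probs = quantileCutoff, names = FALSE)
        conf <- a > q3
        # degenerate ties can leave no cell strictly above the cutoff
        if (sum(conf) == 0L) {
            nTake <- min(length(idx), max(3L, ceiling(0.1 * length(idx))))
            conf <- rank(-a, ties.method = "first") <= nTake
        }
        confident[idx] <- conf
    }
    methods::initialize(clusters,
        confident = confident,
        avgSimilarity = avg
    )
}
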