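#' Configuration of an integration run
#'
#' Collects and validates every tunable of the pipeline. The defaults are the
#' method's standard settings: penalty \code{lambda = 10}, sharing threshold
#' \code{threshold = 0.6}, 40 correction vectors, SNN with k = 20 neighbors
#' on 40 PCs, Leiden resolutions 0.1 to 0.5, confident-cell quantile cutoff
#' 0.75 and library-size scale factor 10,000.
#'
#' @param lambda technical-variation penalty (>= 0).
#' @param threshold cluster-sharing similarity threshold T in (0, 1).
#' @param kVectors maximum number of correction vectors.
#' @param snnK SNN neighborhood size.
#' @param nPCs principal components for the kNN search.
#' @param resolutions Leiden resolution grid.
#' @param quantileCutoff confident-cell quantile in [0.5, 1).
#' @param scaleFactor normalization scale factor.
#' @param minCells,minFeatures QC cutoffs (see \code{\link{filterQC}}).
#' @param nBins,fanoThreshold,meanThreshold HVG selection settings (see
#'   \code{\link{selectHVG}}).
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @return A validated list of class \code{IntegrationConfig}.
#' @export
integrationConfig <- function(lambda = 10, threshold = 0.6, kVectors = 40L,
                              snnK = 20L, nPCs = 40L,
                              resolutions = seq(0.1, 0.5, by = 0.1),
                              quantileCutoff = 0.75, scaleFactor = 1e4,
                              minCells = 3L, minFeatures = 200L,
                              nBins = 20L, fanoThreshold = 0.05,
                              meanThreshold = 0.01, seed = 0L) {
    stopifnot(
        lambda >= 0,
        threshold > 0, threshold < 1,
        quantileCutoff >= 0.5, quantileCutoff < 1,
        kVectors >= 1L, snnK >= 2L, nPCs >= 2L,
        length(resolutions) >= 1L, all(resolutions > 0),
        scaleFactor > 0
    )
    cfg <- list(
        lambda = lambda, threshold = threshold,
        kVectors = as.integer(kVectors), snnK = as.integer(snnK),
        nPCs = as.integer(nPCs), resolutions = resolutions,
        quantileCutoff = quantileCutoff, scaleFactor = scaleFactor,
        minCells = as.integer(minCells), minFeatures = as.integer(minFeatures),
        nBins = as.integer(nBins), fanoThreshold = fanoThreshold,
        meanThreshold = meanThreshold, seed = as.integer(seed)
    )
    class(cfg) <- "IntegrationConfig"
    cfg
}

#' Run the full integration pipeline
#'
#' Executes the eight stages end to end: (1) QC filtering per dataset;
#' (2) log-normalization and HVG selection; (3) consensus Leiden clustering
#' on the per-dataset SNN graphs; (4) confident-cell detection; (5) shared
#' cluster inference across all dataset pairs; (6) confounding-matrix
#' construction; (7) the penalized eigenproblem for the correction vectors;
#' (8) projection of all cells onto them. If no cluster pair passes the
#' sharing threshold, the embedding falls back to the PCA of the
#' confident-cell matrix with a prominent warning.
#'
#' @param datasets named list (>= 2) of nonnegative feature x cell count
#'   matrices; the names are the batch ids.
#' @param config an \code{\link{integrationConfig}}.
#' @return An \linkS4class{IntegrationResult}.
#' @examples
#' \donttest{
#' sim <- simulateFromConfig(simPreset("s1", seed = 1L))
#' res <- runIntegration(sim$datasets, integrationConfig(seed = 1L))
#' res
#' head(cellEmbedding(res)[, 1:3])
#' }
#' @export
runIntegration <- function(datasets, config = integrationConfig()) {
    stopifnot(inherits(config, "IntegrationConfig"))
    if (length(datasets) < 2L) {
        stop("stage input: need at least two datasets")
    }
    if (is.null(names(datasets))) {
        names(datasets) <- paste0("dataset", seq_along(datasets))
    }
    logList <- list(config = unclass(config))

    normList <- lapply(names(datasets), function(b) {
        counts <- tryCatch(
            filterQC(datasets[[b]], config$minCells, config$minFeatures),
            error = function(e) stop("stage qc [", b, "]: ", conditionMessage(e))
        )
        logNormalize(counts, config$scaleFactor)
    })
    names(normList) <- names(datasets)

    hvgList <- lapply(normList, selectHVG,
        nBins = config$nBins,
        fanoThreshold = config$fanoThreshold,
        meanThreshold = config$meanThreshold
    )
    fmList <- intersectFeatures(normList, hvgList)
    logList$nFeatures <- ncol(fmList[[1L]])
    logList$nHVG <- vapply(hvgList, length, integer(1))

    snnList <- list()
    clusterList <- list()
    for (b in names(fmList)) {
        g <- buildSNN(fmList[[b]], k = config$snnK, nPCs = config$nPCs)
        cc <- consensusCluster(g,
            resolutions = config$resolutions,
            seed = .deriveSeed(config$seed, paste0("cluster:", b))
        )
        cc <- detectConfidentCells(g, cc, config$quantileCutoff)
        snnList[[b]] <- g
        clusterList[[b]] <- cc
    }
    logList$nClusters <- vapply(clusterList, function(x) x@nClusters, integer(1))
    logList$nConfident <- vapply(
        clusterList, function(x) sum(x@confident), integer(1)
    )

    pairs <- inferSharedClusters(fmList, clusterList,
        threshold = config$threshold
    )
    logList$pairSimilarities <- pairs@edges$similarity
    if (!any(pairs@edges$passed)) {
        warning(
            "no cluster pair passed the sharing threshold; ",
            "falling back to an uncorrected PCA embedding"
        )
    }

    stacked <- stackConfident(fmList, clusterList)
    y <- buildConfounding(stacked$xhat, stacked$info, pairs,
        seed = config$seed
    )
    basis <- learnCorrection(stacked$xhat, y,
        lambda = config$lambda,
        k = config$kVectors
    )
    logList$technicalRatio <- basis@technicalRatio
    logList$nVectors <- ncol(basis@V)

    xAll <- do.call(rbind, fmList)
    embedding <- projectCells(xAll, basis)
    rownames(embedding) <- unlist(lapply(fmList, rownames), use.names = FALSE)
    batch <- rep(names(fmList), vapply(fmList, nrow, integer(1)))

    methods::new("IntegrationResult",
        embedding = embedding,
        batch = batch,
        basis = basis,
        clusters = clusterList,
        pairs = pairs,
        log = logList
    )
}

#' Project a new dataset into a trained embedding
#'
#' QC-filters and log-normalizes a dataset that was not part of training and
#' projects it onto an existing correction basis (see
#' \code{\link{projectNewData}} for the feature-matching rules).
#'
#' @param counts feature x cell count matrix of the new dataset.
#' @param basis a \linkS4class{CorrectionBasis} or
#'   \linkS4class{IntegrationResult}.
#' @param config an \code{\link{integrationConfig}} (normalization and QC
#'   settings are taken from it).
#' @return Cells x k embedding in the training coordinate frame.
#' @export
projectNewDataset <- function(counts, basis, config = integrationConfig()) {
    if (methods::is(basis, "IntegrationResult")) {
        basis <- basis@basis
    }
    stopifnot(methods::is(basis, "CorrectionBasis"))
    if (is.null(dim(counts)) || any(dim(counts) == 0L)) {
        stop("new dataset is empty")
    }
    counts <- filterQC(counts, config$minCells, config$minFeatures)
    norm <- logNormalize(counts, config$scaleFactor)
    projectNewData(t(norm), basis)
}

#' Export an embedding as TSV
#'
#' Writes the shared embedding with cell ids and batch labels, the format the
#' evaluation helpers read back.
#'
#' @param result an \linkS4class{IntegrationResult}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeEmbeddingTSV <- function(result, path) {
    stopifnot(methods::is(result, "IntegrationResult"))
    df <- data.frame(
        cell_id = rownames(result@embedding),
        batch = result@batch,
        result@embedding,
        check.names = FALSE
    )
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE
    )
    invisible(df)
}

#' Export cluster assignments as TSV
#'
#' One row per cell: batch, consensus cluster, confident flag and average
#' within-cluster SNN similarity.
#'
#' @param result an \linkS4class{IntegrationResult}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeClustersTSV <- function(result, path) {
    stopifnot(methods::is(result, "IntegrationResult"))
    rows <- lapply(names(result@clusters), function(b) {
        cc <- result@clusters[[b]]
        data.frame(
            cell_id = cc@cellIds, batch = b, cluster = cc@labels,
            confident = cc@confident, avg_similarity = cc@avgSimilarity
        )
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE
    )
    invisible(df)
}
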