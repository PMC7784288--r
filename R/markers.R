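#' Marker genes of one cluster (two-part likelihood-ratio test)
#'
#' Compares the confident cells of one cluster against the confident cells of
#' all other clusters of the same dataset with a hurdle-style likelihood-ratio
#' test: one binomial component for the proportion of expressing cells (value
#' strictly positive) and one normal component for the mean log-expression
#' conditional on expression. The LRT statistic is the sum of the two
#' deviances, with p-values from a chi-squared distribution with 2 degrees of
#' freedom. Markers must satisfy p < \code{pCutoff}, log fold-change >
#' \code{logfcCutoff} (natural-log scale, difference of mean log-normalized
#' expression) and expressing fraction inside the cluster > \code{pctCutoff}.
#' No multiple-testing correction is applied.
#'
#' @param fm cells x features log-normalized matrix for one dataset.
#' @param labels integer cluster label per cell.
#' @param confident logical per cell; only confident cells enter the test.
#' @param clusterId the cluster whose markers are sought.
#' @param pCutoff,logfcCutoff,pctCutoff marker thresholds (defaults 0.05,
#'   0.25, 0.25).
#' @return data.frame with columns feature, p_value, log_fc, pct_in, pct_out,
#'   sorted by p-value then decreasing log fold-change.
#' @export
findClusterMarkers <- function(fm, labels, confident, clusterId,
                               pCutoff = 0.05, logfcCutoff = 0.25,
                               pctCutoff = 0.25) {
    fm <- as.matrix(fm)
    n <- nrow(fm)
    stopifnot(length(labels) == n, length(confident) == n)
    inGrp <- confident & labels == clusterId
    outGrp <- confident & labels != clusterId
    if (!any(labels[confident] != clusterId)) {
        stop("no other clusters in the dataset; marker contrast undefined")
    }
    if (sum(inGrp) < 3L) {
        stop("cluster ", clusterId, " has fewer than 3 confident cells")
    }
    x1 <- fm[inGrp, , drop = FALSE]
    x2 <- fm[outGrp, , drop = FALSE]
    n1 <- nrow(x1)
    n2 <- nrow(x2)
    k1 <- colSums(x1 > 0)
    k2 <- colSums(x2 > 0)

    # binomial deviance for the expressing fraction
    devBinom <- .binomDeviance(k1, n1) + .binomDeviance(k2, n2) -
        .binomDeviance(k1 + k2, n1 + n2)

    # normal deviance for the conditional (on expression) mean; zeros do not
    # contribute to the sums, so plain column sums over all cells suffice
    s1 <- colSums(x1)
    s2 <- colSums(x2)
    ss1 <- colSums(x1^2)
    ss2 <- colSums(x2^2)
    k0 <- k1 + k2
    m1 <- ifelse(k1 > 0, s1 / k1, 0)
    m2 <- ifelse(k2 > 0, s2 / k2, 0)
    m0 <- ifelse(k0 > 0, (s1 + s2) / k0, 0)
    rss1 <- pmax(ss1 - k1 * m1^2, 0) + pmax(ss2 - k2 * m2^2, 0)
    rss0 <- pmax(ss1 + ss2 - k0 * m0^2, 0)
    devNorm <- ifelse(
        k1 > 0 & k2 > 0 & rss1 > 0 & k0 > 2,
        k0 * (log(rss0) - log(rss1)),
        0
    )
    stat <- pmax(devBinom, 0) + pmax(devNorm, 0)
    p <- stats::pchisq(stat, df = 2L, lower.tail = FALSE)
    logFc <- colMeans(x1) - colMeans(x2)
    pctIn <- k1 / n1
    pctOut <- k2 / n2

    pass <- p < pCutoff & logFc > logfcCutoff & pctIn > pctCutoff
    out <- data.frame(
        feature = colnames(fm)[pass],
        p_value = p[pass],
        log_fc = logFc[pass],
        pct_in = pctIn[pass],
        pct_out = pctOut[pass],
        row.names = NULL,
        stringsAsFactors = FALSE
    )
    out[order(out$p_value, -out$log_fc), , drop = FALSE]
}

# binomial log-likelihood at the MLE, times 2 (deviance building block)
.binomDeviance <- function(k, n) {
    p <- k / n
    2 * (ifelse(k > 0, k * log(p), 0) +
        ifelse(n - k > 0, (n - k) * log(1 - p), 0))
}

#' Similarity of two cell clusters across datasets
#'
#' Averages two scores: the marker overlap s / min(n1, n2), where s is the
#' number of shared marker genes, and the cosine similarity of the two
#' clusters' mean expression profiles (confident cells) over the union of
#' their marker genes. If either cluster has no markers the overlap is
#' undefined and the similarity falls back to the cosine score alone, with a
#' warning.
#'
#' @param markersP,markersQ marker data.frames from
#'   \code{\link{findClusterMarkers}}.
#' @param meanP,meanQ named numeric vectors of mean log-normalized expression
#'   over each cluster's confident cells (full feature space).
#' @return A list with components \code{overlap}, \code{cosine} and
#'   \code{similarity}, all in [0, 1].
#' @export
clusterSimilarity <- function(markersP, markersQ, meanP, meanQ) {
    mp <- markersP$feature
    mq <- markersQ$feature
    un <- union(mp, mq)
    if (length(un) == 0L) {
        warning("neither cluster has markers; similarity set to 0")
        return(list(overlap = NA_real_, cosine = 0, similarity = 0))
    }
    cosine <- .cosine(
        meanP[match(un, names(meanP))],
        meanQ[match(un, names(meanQ))]
    )
    if (length(mp) == 0L || length(mq) == 0L) {
        warning("a cluster has no markers; using cosine similarity alone")
        return(list(overlap = NA_real_, cosine = cosine, similarity = cosine))
    }
    overlap <- length(intersect(mp, mq)) / min(length(mp), length(mq))
    list(
        overlap = overlap, cosine = cosine,
        similarity = (overlap + cosine) / 2
    )
}

#' Infer shared cell clusters between all dataset pairs
#'
#' Builds the weighted complete bipartite cluster graph for every pair of
#' datasets: markers are found for each cluster on its confident cells, each
#' cross-dataset cluster pair is scored with \code{\link{clusterSimilarity}},
#' and pairs whose similarity strictly exceeds the threshold are declared
#' shared. A cluster can take part in several pairs; clusters in no pair are
#' dataset-specific.
#'
#' @param fmList named list of cells x features matrices (common feature
#'   space), one per dataset.
#' @param clusterList list of \linkS4class{ConsensusClusters}, one per
#'   dataset, with confident cells filled in.
#' @param threshold similarity threshold T (default 0.6, strict inequality).
#' @param ... marker thresholds passed to \code{\link{findClusterMarkers}}.
#' @return A \linkS4class{SharedClusterPairs}.
#' @export
inferSharedClusters <- function(fmList, clusterList, threshold = 0.6, ...) {
    stopifnot(
        length(fmList) >= 2L,
        length(fmList) == length(clusterList)
    )
    ids <- names(fmList)
    if (is.null(ids)) ids <- paste0("dataset", seq_along(fmList))

    perDataset <- lapply(seq_along(fmList), function(d) {
        fm <- as.matrix(fmList[[d]])
        cc <- clusterList[[d]]
        cls <- sort(unique(cc@labels))
        markers <- lapply(cls, function(cl) {
            if (length(cls) == 1L) {
                return(data.frame(feature = character(0)))
            }
            tryCatch(
                findClusterMarkers(fm, cc@labels, cc@confident, cl, ...),
                error = function(e) data.frame(feature = character(0))
            )
        })
        means <- lapply(cls, function(cl) {
            idx <- cc@confident & cc@labels == cl
            colMeans(fm[idx, , drop = FALSE])
        })
        list(clusters = cls, markers = markers, means = means)
    })

    rows <- list()
    for (i in seq_along(fmList)) {
        for (j in seq_along(fmList)) {
            if (j <= i) next
            di <- perDataset[[i]]
            dj <- perDataset[[j]]
            for (a in seq_along(di$clusters)) {
                for (b in seq_along(dj$clusters)) {
                    sim <- suppressWarnings(clusterSimilarity(
                        di$markers[[a]], dj$markers[[b]],
                        di$means[[a]], dj$means[[b]]
                    ))
                    rows[[length(rows) + 1L]] <- data.frame(
                        dataset_i = ids[i],
                        cluster_p = di$clusters[a],
                        dataset_j = ids[j],
                        cluster_q = dj$clusters[b],
                        overlap = ifelse(is.na(sim$overlap), NA_real_,
                            sim$overlap
                        ),
                        cosine = sim$cosine,
                        similarity = sim$similarity,
                        stringsAsFactors = FALSE
                    )
                }
            }
        }
    }
    edges <- do.call(rbind, rows)
    if (is.null(edges)) {
        edges <- data.frame(
            dataset_i = character(0), cluster_p = integer(0),
            dataset_j = character(0), cluster_q = integer(0),
            overlap = numeric(0), cosine = numeric(0),
            similarity = numeric(0)
        )
    }
    edges$passed <- edges$similarity > threshold
    methods::new("SharedClusterPairs", edges = edges, threshold = threshold)
}
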