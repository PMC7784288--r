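#' Agreement between two clusterings
#'
#' Computes four contingency-table metrics between a reference partition and
#' a predicted partition: normalized mutual information (normalized by the
#' arithmetic mean of the two entropies), the adjusted Rand index, the
#' pairwise Jaccard index of co-assigned pairs, and purity (the fraction of
#' cells in the majority reference class of their predicted cluster). All
#' four lie in [0, 1] with 1 a perfect match.
#'
#' @param truth,pred label vectors of equal length (any atomic type).
#' @return Named list with components \code{nmi}, \code{ari}, \code{jaccard},
#'   \code{purity}.
#' @examples
#' clusteringAgreement(rep(1:2, each = 4), rep(c("a", "b"), each = 4))
#' clusteringAgreement(rep(1:2, each = 4), rep(1, 8))
#' @export
clusteringAgreement <- function(truth, pred) {
    stopifnot(length(truth) == length(pred), length(truth) >= 2L)
    n <- length(truth)
    tab <- table(truth, pred)
    a <- rowSums(tab)
    b <- colSums(tab)

    # entropies and mutual information (natural log)
    pa <- a / n
    pb <- b / n
    pab <- tab / n
    ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
    hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
    nz <- pab > 0
    mi <- sum(pab[nz] * log(pab[nz] / (pa[row(tab)][nz] * pb[col(tab)][nz])))
    nmi <- if (ha + hb == 0) {
        1 # both partitions trivial, hence identical
    } else {
        2 * mi / (ha + hb)
    }

    # pair counts
    choose2 <- function(x) x * (x - 1) / 2
    sumNij <- sum(choose2(tab))
    sumAi <- sum(choose2(a))
    sumBj <- sum(choose2(b))
    total <- choose2(n)
    expected <- sumAi * sumBj / total
    denom <- (sumAi + sumBj) / 2 - expected
    ari <- if (denom == 0) {
        if (sumNij == expected) 1 else 0
    } else {
        (sumNij - expected) / denom
    }
    jaccard <- if (sumAi + sumBj - sumNij == 0) {
        1 # no co-assigned pairs on either side
    } else {
        sumNij / (sumAi + sumBj - sumNij)
    }
    purity <- sum(apply(tab, 2L, max)) / n

    list(nmi = nmi, ari = ari, jaccard = jaccard, purity = purity)
}

#' Silhouette score of a labeled embedding
#'
#' For each cell, a(i) is the mean Euclidean distance to the other cells of
#' its cluster and b(i) the smallest mean distance to the cells of any other
#' cluster; s(i) = (b - a) / max(a, b), with s(i) = 0 for singleton clusters.
#' The score is the mean of s(i) over all cells.
#'
#' @param emb cells x d coordinate matrix.
#' @param labels cluster label per cell; at least two distinct values.
#' @return Scalar in [-1, 1].
#' @export
silhouetteScore <- function(emb, labels) {
    emb <- as.matrix(emb)
    n <- nrow(emb)
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
    cls <- unique(labels)
    if (length(cls) < 2L) {
        stop("silhouette needs at least two clusters")
    }
    d <- as.matrix(stats::dist(emb))
    s <- numeric(n)
    sizes <- table(labels)
    # mean distance from every cell to every cluster
    meanTo <- sapply(cls, function(cl) {
        rowSums(d[, labels == cl, drop = FALSE]) / sizes[[cl]]
    })
    for (i in seq_len(n)) {
        sz <- sizes[[labels[i]]]
        if (sz == 1L) {
            s[i] <- 0
            next
        }
        ai <- meanTo[i, labels[i]] * sz / (sz - 1) # exclude self
        bi <- min(meanTo[i, setdiff(cls, labels[i])])
        s[i] <- if (max(ai, bi) == 0) 0 else (bi - ai) / max(ai, bi)
    }
    mean(s)
}

#' Local inverse Simpson's index of label mixing
#'
#' For each cell a Gaussian kernel over its nearest neighbors is tuned by
#' binary search so the neighbor-weight entropy equals log(perplexity); the
#' inverse Simpson's index of the label probabilities under those weights is
#' the cell's raw score (in [1, number of labels]). With batch labels this
#' measures batch mixing (bLISI), with cell-type labels type mixing (cLISI).
#' The summary scalar is the paper-style normalized median,
#' (median - min) / (max - min) over cells.
#'
#' @param emb cells x d coordinate matrix.
#' @param labels label per cell.
#' @param perplexity effective neighborhood size (default 30); the search
#'   uses the 3 * perplexity nearest cells.
#' @return List with \code{normalized} (scalar) and \code{raw} (per-cell
#'   scores).
#' @export
lisiScore <- function(emb, labels, perplexity = 30) {
    emb <- as.matrix(emb)
    n <- nrow(emb)
    stopifnot(length(labels) == n, n >= 3L)
    labels <- as.integer(factor(labels))
    nLab <- max(labels)
    if (nLab < 2L) {
        stop("labels must take at least two values")
    }
    nNbr <- min(n - 1L, as.integer(ceiling(3 * perplexity)))
    nn <- .knnIndices(emb, nNbr)
    target <- log(perplexity)
    raw <- numeric(n)
    for (i in seq_len(n)) {
        d2 <- colSums((t(emb[nn[i, ], , drop = FALSE]) - emb[i, ])^2)
        beta <- 1
        lo <- -Inf
        hi <- Inf
        p <- NULL
        for (iter in 1:50) {
            w <- exp(-beta * (d2 - min(d2)))
            p <- w / sum(w)
            h <- -sum(p[p > 0] * log(p[p > 0]))
            if (abs(h - target) < 1e-5) break
            if (h > target) {
                lo <- beta
                beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
            } else {
                hi <- beta
                beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
            }
        }
        lam <- vapply(
            seq_len(nLab),
            function(l) sum(p[labels[nn[i, ]] == l]), numeric(1)
        )
        raw[i] <- 1 / sum(lam^2)
    }
    spread <- max(raw) - min(raw)
    if (spread == 0) {
        warning("degenerate spread of per-cell scores; normalized score is 0")
        norm <- 0
    } else {
        norm <- (stats::median(raw) - min(raw)) / spread
    }
    list(normalized = norm, raw = raw)
}

#' LISI-derived F1 score
#'
#' Combines normalized batch mixing (bLISI, higher = better mixed) and cell
#' type mixing (cLISI, lower = better separated) into
#' \code{2 * bLISI * (1 - cLISI) / (1 - cLISI + bLISI)}; a zero denominator
#' gives 0.
#'
#' @param blisi,clisi normalized LISI scalars in [0, 1].
#' @return Scalar in [0, 1].
#' @examples
#' lisiF1(1, 0) # perfect mixing and perfect type separation
#' lisiF1(0.5, 0.5)
#' @export
lisiF1 <- function(blisi, clisi) {
    if (blisi < 0 || blisi > 1 || clisi < 0 || clisi > 1) {
        stop("inputs must lie in [0, 1]")
    }
    den <- 1 - clisi + blisi
    if (den == 0) {
        return(0)
    }
    2 * blisi * (1 - clisi) / den
}

#' Specificity score for condition-specific cell types
#'
#' Quantifies how well condition-specific cells stay separate: for each
#' specific cell, the fraction of its k nearest neighbors that are
#' non-specific cells; the score is one minus the median of those fractions.
#'
#' @param emb cells x d coordinate matrix.
#' @param specific logical flag per cell marking the condition-specific
#'   cells.
#' @param k neighborhood size (default 20).
#' @return Scalar in [0, 1]; 1 means specific cells only neighbor each other.
#' @export
specificityScore <- function(emb, specific, k = 20L) {
    emb <- as.matrix(emb)
    n <- nrow(emb)
    stopifnot(length(specific) == n, n >= k + 1L)
    if (!any(specific)) {
        stop("no condition-specific cells flagged")
    }
    nn <- .knnIndices(emb, k)
    idx <- which(specific)
    ratios <- vapply(idx, function(i) sum(!specific[nn[i, ]]) / k, numeric(1))
    1 - stats::median(ratios)
}

#' Pseudotime ordering score and Kendall's tau
#'
#' Over all cell pairs, counts pairs ordered the same way by the inferred
#' pseudotime and the gold standard (concordant, C) and pairs ordered
#' oppositely (discordant, D); POS = C / (C + D). Ties in either vector are
#' neither concordant nor discordant. Kendall's rank correlation is computed
#' with tie correction (tau-b).
#'
#' @param pseudotime,gold numeric vectors of equal length (>= 2).
#' @return List with \code{pos} in [0, 1] and \code{kendall} in [-1, 1].
#' @examples
#' posScore(c(1, 2, 4, 3, 5), 1:5) # one swapped pair: POS = 0.9
#' @export
posScore <- function(pseudotime, gold) {
    stopifnot(length(pseudotime) == length(gold), length(gold) >= 2L)
    if (stats::var(pseudotime) == 0 || stats::var(gold) == 0) {
        stop("all values tied; ordering undefined")
    }
    s1 <- sign(outer(pseudotime, pseudotime, "-"))
    s2 <- sign(outer(gold, gold, "-"))
    up <- upper.tri(s1)
    prod <- s1[up] * s2[up]
    concordant <- sum(prod > 0)
    discordant <- sum(prod < 0)
    list(
        pos = concordant / (concordant + discordant),
        kendall = stats::cor(pseudotime, gold, method = "kendall")
    )
}

#' Fit a principal curve and read off pseudotime
#'
#' Iterated projection-smoothing: pseudotime is initialized from the first
#' principal component, each coordinate is smoothed against pseudotime with
#' lowess (span 0.3 by default), the smoothed points form a polyline, and
#' every cell is orthogonally projected onto it; its arc-length position is
#' the new pseudotime. Iterations stop when the mean projection displacement
#' falls below \code{tol} times the curve length or after \code{maxIter}
#' rounds (with a warning).
#'
#' @param x cells x d coordinate matrix (d >= 2).
#' @param span lowess smoother span (default 0.3).
#' @param maxIter maximum number of projection-smoothing rounds (default 20).
#' @param tol relative displacement threshold for convergence (default 1e-4).
#' @return List with \code{lambda} (arc-length pseudotime per cell),
#'   \code{points} (projected cell positions) and \code{converged}.
#' @export
principalCurve <- function(x, span = 0.3, maxIter = 20L, tol = 1e-4) {
    x <- as.matrix(x)
    n <- nrow(x)
    stopifnot(n >= 5L, ncol(x) >= 2L)
    lambda <- stats::prcomp(x, center = TRUE, rank. = 1L)$x[, 1L]
    proj <- x
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        ord <- order(lambda)
        curve <- apply(x, 2L, function(col) {
            stats::lowess(lambda[ord], col[ord], f = span)$y
        })
        fit <- .projectToPolyline(x, curve)
        disp <- mean(sqrt(rowSums((fit$points - proj)^2)))
        lambda <- fit$lambda
        proj <- fit$points
        if (fit$length > 0 && disp < tol * fit$length) {
            converged <- TRUE
            break
        }
    }
    if (!converged) {
        warning("principal curve did not converge; returning last iterate")
    }
    list(lambda = lambda, points = proj, converged = converged)
}

# Orthogonal projection of points onto the polyline through `curve` rows.
.projectToPolyline <- function(x, curve) {
    # drop consecutive duplicate vertices
    keep <- c(TRUE, rowSums((curve[-1L, , drop = FALSE] -
        curve[-nrow(curve), , drop = FALSE])^2) > 0)
    curve <- curve[keep, , drop = FALSE]
    nSeg <- nrow(curve) - 1L
    if (nSeg < 1L) {
        return(list(
            lambda = numeric(nrow(x)),
            points = matrix(rep(curve[1L, ], each = nrow(x)), nrow(x)),
            length = 0
        ))
    }
    segVec <- curve[-1L, , drop = FALSE] - curve[-nrow(curve), , drop = FALSE]
    segLen2 <- rowSums(segVec^2)
    segLen <- sqrt(segLen2)
    cumLen <- c(0, cumsum(segLen))
    n <- nrow(x)
    best <- rep(Inf, n)
    lambda <- numeric(n)
    pts <- matrix(0, n, ncol(x))
    for (s in seq_len(nSeg)) {
        a <- curve[s, ]
        diff <- sweep(x, 2L, a, "-")
        t <- pmin(1, pmax(0, (diff %*% segVec[s, ]) / segLen2[s]))
        p <- sweep(tcrossprod(t, segVec[s, ]), 2L, a, "+")
        d2 <- rowSums((x - p)^2)
        upd <- d2 < best
        best[upd] <- d2[upd]
        lambda[upd] <- cumLen[s] + t[upd] * segLen[s]
        pts[upd, ] <- p[upd, , drop = FALSE]
    }
    list(lambda = lambda, points = pts, length = cumLen[nSeg + 1L])
}

#' Pseudotime conservation across integration
#'
#' Fits a principal curve to each batch's pre-integration embedding and one
#' to the integrated embedding, reads off arc-length pseudotime, and reports
#' per batch the absolute Pearson correlation between pre- and
#' post-integration pseudotime (curve orientation is arbitrary, so the sign
#' is dropped).
#'
#' @param embBefore named list of per-batch cells x d embeddings
#'   (pre-integration).
#' @param embAfter integrated cells x d embedding covering the same cells,
#'   batch blocks in the same order.
#' @param batches batch label per row of \code{embAfter}.
#' @param ... passed to \code{\link{principalCurve}}.
#' @return Named numeric vector of |Pearson r| per batch.
#' @export
pseudotimeConservation <- function(embBefore, embAfter, batches, ...) {
    embAfter <- as.matrix(embAfter)
    stopifnot(length(batches) == nrow(embAfter))
    after <- principalCurve(embAfter, ...)$lambda
    out <- vapply(names(embBefore), function(b) {
        idx <- which(batches == b)
        stopifnot(length(idx) == nrow(embBefore[[b]]))
        before <- principalCurve(as.matrix(embBefore[[b]]), ...)$lambda
        abs(stats::cor(before, after[idx]))
    }, numeric(1))
    out
}

#' Rank-based overall scores across methods
#'
#' For each metric, methods are ranked in decreasing order of their score and
#' assigned rank points from M (best) down to 1 (worst of M methods); ties
#' share the mean of their point range. The overall score of a method for a
#' category is the mean of its points over that category's metrics; a final
#' column averages over all metrics. Metrics with missing values are skipped
#' for all methods, with a warning.
#'
#' @param metricTable numeric matrix, methods x metrics, with dimnames.
#' @param categoryMap named list mapping category names to metric-name
#'   vectors.
#' @return Numeric matrix methods x (categories + "overall").
#' @export
overallScore <- function(metricTable, categoryMap) {
    metricTable <- as.matrix(metricTable)
    stopifnot(nrow(metricTable) >= 2L, !is.null(colnames(metricTable)))
    bad <- colnames(metricTable)[apply(metricTable, 2L, anyNA)]
    if (length(bad)) {
        warning(
            "metrics with missing values skipped: ",
            paste(bad, collapse = ", ")
        )
        metricTable <- metricTable[, setdiff(colnames(metricTable), bad),
            drop = FALSE
        ]
    }
    m <- nrow(metricTable)
    points <- apply(metricTable, 2L, function(x) {
        m + 1 - rank(-x, ties.method = "average")
    })
    if (is.null(dim(points))) points <- matrix(points, nrow = m)
    rownames(points) <- rownames(metricTable)
    colnames(points) <- colnames(metricTable)
    cats <- c(categoryMap, list(overall = colnames(metricTable)))
    out <- sapply(cats, function(metrics) {
        metrics <- intersect(metrics, colnames(points))
        if (length(metrics) == 0L) {
            return(rep(NA_real_, m))
        }
        rowMeans(points[, metrics, drop = FALSE])
    })
    rownames(out) <- rownames(metricTable)
    out
}
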