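#' Stack confident cells across datasets
#'
#' Assembles the confident-cell matrix used to learn the correction: the rows
#' of every dataset's feature matrix restricted to its confident cells,
#' stacked in dataset order, together with a per-row record of the dataset
#' and cluster each confident cell came from.
#'
#' @param fmList named list of cells x features matrices over the common
#'   feature space.
#' @param clusterList list of \linkS4class{ConsensusClusters} with confident
#'   cells filled in, one per dataset.
#' @return List with \code{xhat} (confident cells x features matrix) and
#'   \code{info} (data.frame with columns dataset, cluster, cell).
#' @export
stackConfident <- function(fmList, clusterList) {
    stopifnot(length(fmList) == length(clusterList))
    ids <- names(fmList)
    if (is.null(ids)) ids <- paste0("dataset", seq_along(fmList))
    parts <- lapply(seq_along(fmList), function(d) {
        cc <- clusterList[[d]]
        idx <- which(cc@confident)
        list(
            x = as.matrix(fmList[[d]])[idx, , drop = FALSE],
            info = data.frame(
                dataset = ids[d],
                cluster = cc@labels[idx],
                cell = cc@cellIds[idx],
                stringsAsFactors = FALSE
            )
        )
    })
    list(
        xhat = do.call(rbind, lapply(parts, `[[`, "x")),
        info = do.call(rbind, lapply(parts, `[[`, "info"))
    )
}

#' Build the confounding matrix from shared cluster pairs
#'
#' Encodes the inferred technical variation as a signed index matrix Y with
#' one disjoint column block per shared cluster pair. For a pair with
#' n_p and n_q confident cells, the larger side is downsampled uniformly
#' without replacement to n_pq = min(n_p, n_q); both sides are put in a
#' seeded-shuffled order and matched position by position, so that column t
#' of the pair's block carries +1 at the t-th cell of cluster p and -1 at the
#' t-th cell of cluster q. The rows of t(Y) %*% xhat are then exactly the
#' paired difference vectors whose squared norm is the technical variation.
#' The per-pair shuffling seed is derived from the unordered pair identity,
#' making Y invariant to the order datasets are supplied in.
#'
#' @param xhat confident cells x features matrix from
#'   \code{\link{stackConfident}}.
#' @param info data.frame (dataset, cluster) per row of \code{xhat}.
#' @param pairs a \linkS4class{SharedClusterPairs}.
#' @param seed master integer seed.
#' @return Sparse n x l matrix Y with entries in \{-1, 0, 1\}; attribute
#'   \code{"blocks"} maps each pair to its column range. l = sum over pairs
#'   of n_pq. Zero-column matrix if no pair passed the threshold.
#' @export
buildConfounding <- function(xhat, info, pairs, seed = 0L) {
    stopifnot(nrow(xhat) == nrow(info))
    shared <- sharedPairs(pairs)
    n <- nrow(xhat)
    triplets <- list()
    blocks <- list()
    colOffset <- 0L
    for (r in seq_len(nrow(shared))) {
        e <- shared[r, ]
        rowsP <- which(info$dataset == e$dataset_i & info$cluster == e$cluster_p)
        rowsQ <- which(info$dataset == e$dataset_j & info$cluster == e$cluster_q)
        if (length(rowsP) == 0L || length(rowsQ) == 0L) {
            warning(
                "pair (", e$dataset_i, ":", e$cluster_p, ", ",
                e$dataset_j, ":", e$cluster_q,
                ") has a side with no confident cells; skipped"
            )
            next
        }
        keyP <- paste0(e$dataset_i, ":", e$cluster_p)
        keyQ <- paste0(e$dataset_j, ":", e$cluster_q)
        tag <- paste(sort(c(keyP, keyQ)), collapse = "~")
        npq <- min(length(rowsP), length(rowsQ))
        ordP <- withr::with_seed(
            .deriveSeed(seed, paste0(tag, "#", keyP)),
            sample(length(rowsP))
        )[seq_len(npq)]
        ordQ <- withr::with_seed(
            .deriveSeed(seed, paste0(tag, "#", keyQ)),
            sample(length(rowsQ))
        )[seq_len(npq)]
        triplets[[length(triplets) + 1L]] <- data.frame(
            i = c(rowsP[ordP], rowsQ[ordQ]),
            j = rep(colOffset + seq_len(npq), 2L),
            x = rep(c(1, -1), each = npq)
        )
        blocks[[tag]] <- c(colOffset + 1L, colOffset + npq)
        colOffset <- colOffset + npq
    }
    if (length(triplets) == 0L) {
        y <- Matrix::sparseMatrix(
            i = integer(0), j = integer(0), x = numeric(0),
            dims = c(n, 0L)
        )
    } else {
        tr <- do.call(rbind, triplets)
        y <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, colOffset))
    }
    attr(y, "blocks") <- blocks
    y
}

#' Learn correction vectors from the penalized eigenproblem
#'
#' Solves for the directions that maximize total variation minus
#' \code{lambda} times the technical variation: the eigenvectors of the
#' symmetric m x m matrix \code{A = t(Xc) Xc - lambda t(Xc) Y t(Y) Xc}
#' (Xc the column-centered confident-cell matrix) associated with the largest
#' strictly positive eigenvalues, at most k of them. With \code{lambda = 0} or
#' an empty pair set this reduces to PCA of the confident-cell matrix. The
#' sign of each vector is fixed so its largest-magnitude entry is positive.
#'
#' @param xhat confident cells x features matrix.
#' @param y confounding matrix from \code{\link{buildConfounding}} (n x l,
#'   possibly zero columns).
#' @param lambda penalty controlling the strength of technical-variation
#'   subtraction (default 10).
#' @param k maximum number of correction vectors (default 40).
#' @param center if TRUE (default) columns of \code{xhat} are centered before
#'   forming the eigenproblem and the centering vector is stored for
#'   projection.
#' @return A \linkS4class{CorrectionBasis}.
#' @export
learnCorrection <- function(xhat, y, lambda = 10, k = 40L, center = TRUE) {
    xhat <- as.matrix(xhat)
    m <- ncol(xhat)
    if (m < 2L) {
        stop("need at least 2 features")
    }
    stopifnot(nrow(y) == nrow(xhat), lambda >= 0)
    ctr <- if (center) colMeans(xhat) else numeric(m)
    xc <- .centerColumns(xhat, ctr)
    yx <- as.matrix(Matrix::crossprod(y, xc)) # l x m paired differences
    a <- crossprod(xc) - lambda * crossprod(yx)
    a <- (a + t(a)) / 2
    if (max(abs(a - t(a))) > 1e-10) {
        stop("eigenproblem matrix failed the symmetry check")
    }
    es <- eigen(a, symmetric = TRUE)
    tol <- max(abs(es$values)) * 1e-12
    pos <- which(es$values > tol)
    if (length(pos) == 0L) {
        stop("technical variation dominates; lower lambda")
    }
    if (length(pos) < k) {
        warning(
            "only ", length(pos), " positive eigenvalues available (",
            k, " requested)"
        )
    }
    keep <- pos[seq_len(min(k, length(pos)))]
    v <- es$vectors[, keep, drop = FALSE]
    # deterministic sign: largest-magnitude entry of each column positive
    for (i in seq_len(ncol(v))) {
        j <- which.max(abs(v[, i]))
        if (v[j, i] < 0) v[, i] <- -v[, i]
    }
    featureIds <- colnames(xhat)
    if (is.null(featureIds)) featureIds <- paste0("feature", seq_len(m))
    rownames(v) <- featureIds
    colnames(v) <- paste0("CV", seq_len(ncol(v)))
    basis <- methods::new("CorrectionBasis",
        V = v,
        eigenvalues = es$values[keep],
        lambda = lambda,
        center = unname(ctr),
        featureIds = featureIds,
        technicalRatio = 0
    )
    methods::initialize(basis,
        technicalRatio = technicalRatio(xhat, y, basis)
    )
}

#' Technical-variation ratio
#'
#' The share of technical variation among the total variation captured by the
#' correction vectors:
#' \code{R = tr(V' X' Y Y' X V) / (tr(V' X' Y Y' X V) + tr(V' X' X V))},
#' computed with the same centering as the basis. R is always in [0, 1] and
#' equals 0 when Y has no columns.
#'
#' @param xhat confident cells x features matrix.
#' @param y confounding matrix.
#' @param basis a \linkS4class{CorrectionBasis} (its V and centering vector
#'   are used).
#' @return Numeric scalar in [0, 1].
#' @export
technicalRatio <- function(xhat, y, basis) {
    stopifnot(methods::is(basis, "CorrectionBasis"))
    xc <- .centerColumns(as.matrix(xhat), basis@center)
    p <- xc %*% basis@V
    den <- sum(p^2)
    if (den == 0) {
        stop("projected data is identically zero; ratio undefined")
    }
    num <- sum(as.matrix(Matrix::crossprod(y, p))^2)
    num / (num + den)
}

#' Project cells onto the correction vectors
#'
#' Computes the shared embedding \code{L = (X - center) V} for all cells
#' (confident or not, matched or dataset-specific alike).
#'
#' @param x cells x features matrix whose columns match the basis features
#'   exactly (order included).
#' @param basis a \linkS4class{CorrectionBasis}.
#' @return Cells x k embedding matrix.
#' @export
projectCells <- function(x, basis) {
    x <- as.matrix(x)
    if (!identical(colnames(x), basis@featureIds)) {
        missing <- setdiff(basis@featureIds, colnames(x))
        if (length(missing)) {
            stop(
                "features missing from input: ",
                paste(utils::head(missing, 10L), collapse = ", ")
            )
        }
        x <- x[, basis@featureIds, drop = FALSE]
    }
    .centerColumns(x, basis@center) %*% basis@V
}

#' Project a new dataset into an existing embedding
#'
#' Applies a previously learned correction basis to a dataset that was not
#' part of training (normalized the same way). Basis features absent from the
#' new dataset contribute zero to the projection (they are imputed at the
#' training center), with a warning; more than half missing is an error.
#'
#' @param xNew cells x features matrix of the new dataset (log-normalized).
#' @param basis a \linkS4class{CorrectionBasis}.
#' @return Cells x k embedding in the same coordinate frame as the training
#'   embedding.
#' @export
projectNewData <- function(xNew, basis) {
    xNew <- as.matrix(xNew)
    if (is.null(colnames(xNew))) {
        stop("new dataset must carry feature names")
    }
    hit <- basis@featureIds %in% colnames(xNew)
    if (mean(hit) < 0.5) {
        stop(
            sum(!hit), " of ", length(hit),
            " basis features missing from the new dataset"
        )
    }
    if (any(!hit)) {
        warning(
            sum(!hit), " basis features missing; ",
            "their contribution is zero-filled"
        )
    }
    full <- matrix(0, nrow(xNew), length(basis@featureIds),
        dimnames = list(rownames(xNew), basis@featureIds)
    )
    present <- basis@featureIds[hit]
    full[, present] <- xNew[, present]
    # missing features sit at the training center so they contribute nothing
    full[, !hit] <- rep(basis@center[!hit], each = nrow(xNew))
    .centerColumns(full, basis@center) %*% basis@V
}
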