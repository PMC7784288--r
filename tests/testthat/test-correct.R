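test_that("confounding matrix columns carry exactly one +1 and one -1", {
    withr::with_seed(41L, {
        x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(
            paste0("c", 1:6), paste0("f", 1:4)
        ))
    })
    info <- data.frame(
        dataset = rep(c("b1", "b2"), each = 3L),
        cluster = rep(1L, 6L)
    )
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = 1L, dataset_j = "b2", cluster_q = 1L,
        overlap = 1, cosine = 1, similarity = 0.9
    ))
    y <- buildConfounding(x, info, pairs, seed = 1L)
    expect_equal(dim(y), c(6L, 3L)) # n_pq = min(3, 3)
    expect_equal(as.matrix(Matrix::crossprod(y)), 2 * diag(3), ignore_attr = TRUE)
    expect_true(all(Matrix::colSums(y == 1) == 1))
    expect_true(all(Matrix::colSums(y == -1) == 1))
    # +1 rows from cluster p's side, -1 rows from cluster q's side
    ym <- as.matrix(y)
    expect_true(all(which(rowSums(ym == 1) > 0) %in% 1:3))
    expect_true(all(which(rowSums(ym == -1) > 0) %in% 4:6))
})

test_that("the quadratic form equals the explicit sum over paired differences", {
    withr::with_seed(42L, {
        nC <- c(3L, 5L, 4L, 6L)
        x <- matrix(rnorm(sum(nC) * 7), sum(nC), 7)
        colnames(x) <- paste0("f", 1:7)
    })
    info <- data.frame(
        dataset = rep(c("b1", "b1", "b2", "b2"), nC),
        cluster = rep(c(1L, 2L, 1L, 2L), nC)
    )
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = c(1L, 2L),
        dataset_j = "b2", cluster_q = c(1L, 2L),
        overlap = 1, cosine = 1, similarity = 0.95
    ))
    y <- buildConfounding(x, info, pairs, seed = 3L)
    # l = sum over pairs of min(n_p, n_q) = 3 + 5
    expect_equal(ncol(y), 8L)

    # oracle: read the matching off Y's columns (structure verified above)
    # and accumulate the per-pair difference quadratic forms directly
    ym <- as.matrix(y)
    acc <- matrix(0, 7, 7)
    diffs <- matrix(0, ncol(y), 7)
    for (t in seq_len(ncol(y))) {
        ip <- which(ym[, t] == 1)
        iq <- which(ym[, t] == -1)
        d <- x[ip, ] - x[iq, ]
        diffs[t, ] <- d
        acc <- acc + tcrossprod(d)
    }
    lhs <- as.matrix(Matrix::crossprod(x, y) %*% Matrix::crossprod(y, x))
    expect_lt(max(abs(lhs - acc)), 1e-10)
    expect_equal(as.matrix(Matrix::crossprod(y, x)), diffs,
        ignore_attr = TRUE
    )
})

test_that("pairs with an empty side are skipped with a warning", {
    x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3)))
    info <- data.frame(dataset = rep(c("b1", "b2"), each = 2L), cluster = 1L)
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = c(1L, 9L), dataset_j = "b2",
        cluster_q = c(1L, 9L), overlap = 1, cosine = 1, similarity = 0.9
    ))
    expect_warning(y <- buildConfounding(x, info, pairs, seed = 1L), "skipped")
    expect_equal(ncol(y), 2L)
})

test_that("with lambda 0 or empty pairs the correction is exactly PCA", {
    withr::with_seed(43L, {
        # anisotropic columns give a clean eigengap at every cutoff
        x <- matrix(rnorm(80 * 12), 80, 12) %*% diag(seq(4, 1, length.out = 12))
        colnames(x) <- paste0("f", 1:12)
    })
    yEmpty <- Matrix::sparseMatrix(
        i = integer(0), j = integer(0), x = numeric(0), dims = c(80L, 0L)
    )
    k <- 5L
    ref <- stats::prcomp(x, center = TRUE)$rotation[, 1:k]
    b0 <- learnCorrection(x, yEmpty, lambda = 0, k = k)
    expect_lt(maxPrincipalAngle(correctionVectors(b0), ref), 1e-8)

    # nonzero Y but lambda = 0 is the same subspace
    info <- data.frame(dataset = rep(c("b1", "b2"), each = 40L), cluster = 1L)
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = 1L, dataset_j = "b2", cluster_q = 1L,
        overlap = 1, cosine = 1, similarity = 0.9
    ))
    y <- buildConfounding(x, info, pairs, seed = 1L)
    b1 <- learnCorrection(x, y, lambda = 0, k = k)
    expect_lt(maxPrincipalAngle(correctionVectors(b1), ref), 1e-8)
    expect_equal(technicalRatioOf(b0), 0)
})

test_that("two-feature toy flips its leading vector as lambda grows", {
    # two clusters per batch: batch offset along feature 1 (5 units),
    # biology separating the clusters along feature 2 (4 units)
    withr::with_seed(44L, {
        n <- 25L
        mkBlock <- function(bShift, gShift) {
            cbind(
                f1 = rnorm(n, bShift, 0.2),
                f2 = rnorm(n, gShift, 0.2)
            )
        }
        x <- rbind(
            mkBlock(0, 0), mkBlock(0, 4), # batch 1, clusters 1/2
            mkBlock(5, 0), mkBlock(5, 4) # batch 2, clusters 1/2
        )
    })
    info <- data.frame(
        dataset = rep(c("b1", "b2"), each = 2L * n),
        cluster = rep(c(1L, 2L, 1L, 2L), each = n)
    )
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = c(1L, 2L), dataset_j = "b2",
        cluster_q = c(1L, 2L), overlap = 1, cosine = 1, similarity = 0.9
    ))
    y <- buildConfounding(x, info, pairs, seed = 2L)
    bSmall <- learnCorrection(x, y, lambda = 0, k = 2L)
    bLarge <- suppressWarnings(learnCorrection(x, y, lambda = 10, k = 2L))
    expect_gt(abs(correctionVectors(bSmall)[1, 1]), 0.95) # ~ e1
    expect_gt(abs(correctionVectors(bLarge)[2, 1]), 0.95) # ~ e2

    # dense brute-force eigendecomposition agreement
    xc <- scale(x, center = TRUE, scale = FALSE)
    a <- crossprod(xc) - 10 * crossprod(as.matrix(Matrix::crossprod(y, xc)))
    ev <- eigen((a + t(a)) / 2, symmetric = TRUE)
    keep <- ev$values > max(abs(ev$values)) * 1e-12
    expect_equal(bLarge@eigenvalues, ev$values[keep], tolerance = 1e-8)
})

test_that("eigenproblem matches brute force for moderate feature counts", {
    withr::with_seed(45L, {
        x <- matrix(rnorm(120 * 40), 120, 40)
        colnames(x) <- paste0("f", 1:40)
    })
    info <- data.frame(dataset = rep(c("b1", "b2"), each = 60L), cluster = 1L)
    pairs <- makePairs(data.frame(
        dataset_i = "b1", cluster_p = 1L, dataset_j = "b2", cluster_q = 1L,
        overlap = 1, cosine = 1, similarity = 0.9
    ))
    y <- buildConfounding(x, info, pairs, seed = 5L)
    b <- suppressWarnings(learnCorrection(x, y, lambda = 2, k = 10L))
    xc <- scale(x, center = TRUE, scale = FALSE)
    a <- crossprod(xc) - 2 * crossprod(as.matrix(Matrix::crossprod(y, xc)))
    ev <- eigen((a + t(a)) / 2, symmetric = TRUE)$values
    expect_equal(b@eigenvalues, ev[seq_len(length(b@eigenvalues))],
        tolerance = 1e-8
    )
    # orthonormal, descending, positive
    expect_true(all(diff(b@eigenvalues) <= 1e-8))
    expect_true(all(b@eigenvalues > 0))
    expect_equal(crossprod(correctionVectors(b)),
        diag(ncol(correctionVectors(b))),
        ignore_attr = TRUE, tolerance = 1e-10
    )
})

test_that("technical ratio is a bounded trace ratio and zero without pairs", {
    toy <- makeShiftToy()
    yEmpty <- Matrix::sparseMatrix(
        i = integer(0), j = integer(0), x = numeric(0),
        dims = c(nrow(toy$x), 0L)
    )
    b0 <- learnCorrection(toy$x, yEmpty, lambda = 0, k = 4L)
    expect_equal(technicalRatio(toy$x, yEmpty, b0), 0)

    # scalar recomputation via explicit projections
    y <- buildConfounding(toy$x, toy$info, toy$pairs, seed = 1L)
    b <- suppressWarnings(learnCorrection(toy$x, y, lambda = 10, k = 4L))
    xc <- sweep(toy$x, 2, b@center)
    p <- xc %*% correctionVectors(b)
    num <- sum((as.matrix(Matrix::t(y)) %*% p)^2)
    den <- sum(p^2)
    expect_equal(technicalRatio(toy$x, y, b), num / (num + den),
        tolerance = 1e-12
    )

    # bounds on random instances
    withr::with_seed(46L, {
        for (i in 1:20) {
            n <- sample(20:40, 1)
            m <- sample(5:10, 1)
            x <- matrix(rnorm(2 * n * m), 2 * n, m,
                dimnames = list(NULL, paste0("f", 1:m))
            )
            info <- data.frame(
                dataset = rep(c("b1", "b2"), each = n), cluster = 1L
            )
            pairs <- makePairs(data.frame(
                dataset_i = "b1", cluster_p = 1L, dataset_j = "b2",
                cluster_q = 1L, overlap = 1, cosine = 1, similarity = 0.9
            ))
            y <- buildConfounding(x, info, pairs, seed = i)
            b <- suppressWarnings(
                learnCorrection(x, y, lambda = runif(1, 0, 0.4), k = 3L)
            )
            r <- technicalRatio(x, y, b)
            expect_gte(r, 0)
            expect_lte(r, 1)
        }
    })
})

test_that("projection is the centered matrix product", {
    withr::with_seed(47L, {
        x <- matrix(rnorm(30 * 6), 30, 6,
            dimnames = list(paste0("c", 1:30), paste0("f", 1:6))
        )
    })
    v <- diag(6)[, 1:3]
    b <- methods::new("CorrectionBasis",
        V = matrix(v, 6, 3, dimnames = list(paste0("f", 1:6), paste0("CV", 1:3))),
        eigenvalues = c(3, 2, 1), lambda = 0,
        center = rep(0, 6), featureIds = paste0("f", 1:6),
        technicalRatio = 0
    )
    l <- projectCells(x, b)
    expect_equal(l, x[, 1:3], ignore_attr = TRUE) # identity columns
    x0 <- x
    x0[5, ] <- 0
    expect_equal(unname(projectCells(x0, b)[5, ]), rep(0, 3))
    # per-cell dot-product loop oracle
    withr::with_seed(48L, {
        vv <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
    })
    rownames(vv) <- paste0("f", 1:6)
    b2 <- methods::new("CorrectionBasis",
        V = vv, eigenvalues = c(3, 2, 1), lambda = 0,
        center = colMeans(x), featureIds = paste0("f", 1:6),
        technicalRatio = 0
    )
    l2 <- projectCells(x, b2)
    for (i in c(1, 7, 30)) {
        for (j in 1:3) {
            expect_equal(unname(l2[i, j]),
                sum((x[i, ] - colMeans(x)) * vv[, j]),
                tolerance = 1e-12
            )
        }
    }
    expect_error(projectCells(x[, 1:4], b2), "missing")
})

test_that("new datasets project into the training frame", {
    toy <- makeShiftToy()
    y <- buildConfounding(toy$x, toy$info, toy$pairs, seed = 1L)
    b <- suppressWarnings(learnCorrection(toy$x, y, lambda = 10, k = 3L))
    # projecting the training data reproduces the training embedding
    expect_equal(projectNewData(toy$x, b), projectCells(toy$x, b))
    # zero-filled missing features shrink the norm, stay finite
    drop <- toy$x[, 1:15]
    expect_warning(lNew <- projectNewData(drop, b), "zero-filled")
    expect_true(all(is.finite(lNew)))
    lFull <- projectCells(toy$x, b)
    expect_lte(
        mean(sqrt(rowSums(lNew^2))) / mean(sqrt(rowSums(lFull^2))), 1 + 1e-8
    )
    expect_error(projectNewData(toy$x[, 1:5], b), "missing from the new dataset")
})

test_that("batch-shift toy: batch centroids collapse, biology is preserved", {
    toy <- makeShiftToy()
    y <- buildConfounding(toy$x, toy$info, toy$pairs, seed = 1L)
    b0 <- learnCorrection(toy$x, y, lambda = 0, k = 5L)
    b10 <- suppressWarnings(learnCorrection(toy$x, y, lambda = 10, k = 5L))
    l0 <- projectCells(toy$x, b0)
    l10 <- projectCells(toy$x, b10)
    batchDist <- function(l) {
        euclid(centroid(l, toy$batch == "b1"), centroid(l, toy$batch == "b2"))
    }
    popDist <- function(l) {
        euclid(centroid(l, toy$pop == "p1"), centroid(l, toy$pop == "p2"))
    }
    expect_gte(batchDist(l0) / batchDist(l10), 10)
    expect_lt(abs(popDist(l10) - popDist(l0)) / popDist(l0), 0.2)
    expect_lt(technicalRatioOf(b10), technicalRatioOf(b0) + 1e-12)
})

test_that("dataset order does not change the learned spectrum", {
    toy <- makeShiftToy()
    y1 <- buildConfounding(toy$x, toy$info, toy$pairs, seed = 9L)
    # flip the roles of the two datasets in the pair table
    flipped <- toy$pairs@edges
    flipped[, c("dataset_i", "dataset_j")] <-
        flipped[, c("dataset_j", "dataset_i")]
    flipped[, c("cluster_p", "cluster_q")] <-
        flipped[, c("cluster_q", "cluster_p")]
    pairs2 <- makePairs(flipped)
    y2 <- buildConfounding(toy$x, toy$info, pairs2, seed = 9L)
    b1 <- suppressWarnings(learnCorrection(toy$x, y1, lambda = 5, k = 4L))
    b2 <- suppressWarnings(learnCorrection(toy$x, y2, lambda = 5, k = 4L))
    expect_equal(b1@eigenvalues, b2@eigenvalues, tolerance = 1e-10)
    expect_lt(
        maxPrincipalAngle(correctionVectors(b1), correctionVectors(b2)), 1e-6
    )
})
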