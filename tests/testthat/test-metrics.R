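test_that("clustering agreement matches exhaustive pair counting", {
    # perfect match under relabeling
    truth <- rep(1:3, times = c(5, 7, 4))
    pred <- c("c", "a", "b")[truth]
    ag <- clusteringAgreement(truth, pred)
    expect_equal(ag$nmi, 1)
    expect_equal(ag$ari, 1)
    expect_equal(ag$jaccard, 1)
    expect_equal(ag$purity, 1)

    # one big cluster vs 2 equal clusters of 4
    truth <- rep(1:2, each = 4)
    pred <- rep(1, 8)
    ag <- clusteringAgreement(truth, pred)
    expect_equal(ag$purity, 0.5)
    expect_equal(ag$jaccard, 12 / 28) # 12 true pairs of C(8,2)=28 predicted

    # random labelings against the brute-force oracle
    withr::with_seed(51L, {
        for (i in 1:10) {
            n <- sample(10:50, 1)
            t1 <- sample(1:4, n, replace = TRUE)
            p1 <- sample(1:5, n, replace = TRUE)
            ag <- clusteringAgreement(t1, p1)
            br <- bruteAgreement(t1, p1)
            expect_equal(ag$ari, br$ari, tolerance = 1e-12)
            expect_equal(ag$jaccard, br$jaccard, tolerance = 1e-12)
            expect_equal(ag$purity, br$purity, tolerance = 1e-12)
            expect_equal(ag$nmi, br$nmi, tolerance = 1e-12)
        }
    })
})

test_that("agreement metrics agree with independent library implementations", {
    skip_if_not_installed("mclust")
    withr::with_seed(52L, {
        t1 <- sample(1:3, 40, replace = TRUE)
        p1 <- sample(1:4, 40, replace = TRUE)
    })
    ag <- clusteringAgreement(t1, p1)
    expect_equal(ag$ari, mclust::adjustedRandIndex(t1, p1), tolerance = 1e-10)
    expect_equal(ag$nmi, igraph::compare(t1, p1, method = "nmi"),
        tolerance = 1e-10
    )
})

test_that("agreement is invariant to label renaming and handles degeneracy", {
    withr::with_seed(53L, {
        t1 <- sample(1:3, 30, replace = TRUE)
        p1 <- sample(1:3, 30, replace = TRUE)
    })
    a1 <- clusteringAgreement(t1, p1)
    a2 <- clusteringAgreement(c(9, 5, 7)[t1], c("x", "y", "z")[p1])
    expect_equal(a1, a2)
    # single label on both sides
    expect_equal(clusteringAgreement(rep(1, 5), rep("a", 5))$nmi, 1)
})

test_that("silhouette matches hand and quadratic-time reference evaluation", {
    # 6-point configuration, hand-checkable
    emb <- matrix(c(
        0, 0, 0, 1, 1, 0,
        10, 0, 10, 1, 11, 0
    ), ncol = 2, byrow = TRUE)
    labels <- rep(1:2, each = 3)
    expect_equal(silhouetteScore(emb, labels), bruteSilhouette(emb, labels),
        tolerance = 1e-12
    )
    expect_gt(silhouetteScore(emb, labels), 0.8) # tight, well separated

    # random configurations against the reference, including singletons
    withr::with_seed(54L, {
        for (i in 1:5) {
            n <- sample(20:60, 1)
            emb <- matrix(rnorm(2 * n), n, 2)
            labels <- sample(1:4, n, replace = TRUE)
            expect_equal(
                silhouetteScore(emb, labels),
                bruteSilhouette(emb, labels),
                tolerance = 1e-12
            )
        }
    })
    expect_error(silhouetteScore(emb, rep(1, nrow(emb))), "two clusters")
})

test_that("silhouette agrees with the cluster package on clean labelings", {
    skip_if_not_installed("cluster")
    withr::with_seed(55L, {
        emb <- matrix(rnorm(120), 60, 2)
        labels <- rep(1:3, each = 20)
    })
    ref <- mean(cluster::silhouette(labels, dist(emb))[, "sil_width"])
    expect_equal(silhouetteScore(emb, labels), ref, tolerance = 1e-10)
})

test_that("raw LISI reflects mixing and stays within its range", {
    # perfectly mixed two-batch lattice
    withr::with_seed(56L, {
        n <- 200L
        emb <- matrix(rnorm(2 * n, sd = 1), n, 2)
        batch <- rep(1:2, n / 2)
    })
    l <- lisiScore(emb, batch, perplexity = 30)
    expect_lt(abs(median(l$raw) - 2), 0.1) # near 2 everywhere
    expect_true(all(l$raw >= 1 - 1e-9 & l$raw <= 2 + 1e-9))

    # fully separated batches: interior cells near 1
    sep <- rbind(emb[1:100, ], emb[101:200, ] + 50)
    l2 <- lisiScore(sep, rep(1:2, each = 100), perplexity = 10)
    expect_lt(median(l2$raw), 1.05)
    expect_true(all(l2$raw >= 1 - 1e-9))
})

test_that("LISI normalization is the scaled median", {
    withr::with_seed(57L, {
        emb <- matrix(rnorm(300), 150, 2)
        lab <- sample(1:3, 150, replace = TRUE)
    })
    l <- lisiScore(emb, lab, perplexity = 15)
    expect_equal(
        l$normalized,
        (median(l$raw) - min(l$raw)) / (max(l$raw) - min(l$raw))
    )
})

test_that("LISI-derived F1 obeys its endpoint identities", {
    expect_equal(lisiF1(1, 0), 1)
    expect_equal(lisiF1(0, 0.3), 0)
    expect_equal(lisiF1(0.5, 0.5), 0.5)
    expect_equal(lisiF1(0, 1), 0) # zero denominator
    expect_error(lisiF1(1.2, 0), "\\[0, 1\\]")
})

test_that("specificity scores isolation of condition-specific cells", {
    withr::with_seed(58L, {
        others <- matrix(rnorm(200, sd = 0.5), 100, 2)
        clump <- matrix(rnorm(60, sd = 0.3), 30, 2) + 50
    })
    emb <- rbind(others, clump)
    specific <- c(rep(FALSE, 100), rep(TRUE, 30))
    expect_equal(specificityScore(emb, specific, k = 20), 1)

    # specific cells interleaved 1:1 on a line: about half the neighbors
    # of each specific cell are non-specific
    line <- cbind(seq_len(200), 0)
    inter <- rep(c(TRUE, FALSE), 100)
    s <- specificityScore(line, inter, k = 20)
    expect_lt(abs(s - 0.5), 0.06)

    # each specific cell surrounded only by others
    lone <- cbind(c(0, seq(10, 200, by = 10)), 0)
    flag <- c(TRUE, rep(FALSE, 20))
    expect_equal(specificityScore(lone, flag, k = 5), 0)

    # rigid transformation invariance
    theta <- 0.7
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    expect_equal(
        specificityScore(emb %*% rot + 5, specific, k = 20),
        specificityScore(emb, specific, k = 20)
    )
    expect_error(specificityScore(emb, rep(FALSE, 130)), "no condition")
})

test_that("POS counts concordant pair fractions", {
    expect_equal(posScore(1:5, 1:5), list(pos = 1, kendall = 1))
    expect_equal(posScore(5:1, 1:5), list(pos = 0, kendall = -1))
    # one swap in 5 elements: 9 concordant, 1 discordant
    swapped <- c(1, 2, 4, 3, 5)
    expect_equal(posScore(swapped, 1:5)$pos, 0.9)
    expect_equal(posScore(swapped, 1:5)$pos, brutePOS(swapped, 1:5))
    # invariance to strictly monotone transforms; ties excluded
    withr::with_seed(59L, {
        a <- rnorm(30)
        b <- rnorm(30)
    })
    expect_equal(posScore(a, b)$pos, posScore(exp(a), b^3)$pos)
    expect_equal(posScore(a, b)$pos, brutePOS(a, b))
    withTies <- c(1, 1, 2, 3)
    expect_equal(posScore(withTies, c(1, 2, 3, 4))$pos, 1) # ties neutral
    expect_error(posScore(rep(1, 4), 1:4), "tied")
})

test_that("principal-curve pseudotime is invariant to isometries", {
    withr::with_seed(60L, {
        t <- sort(runif(150))
        line <- cbind(10 * t, 5 * t) + matrix(rnorm(300, sd = 0.01), 150, 2)
    })
    pc <- principalCurve(line)
    expect_gt(abs(cor(pc$lambda, t)), 0.999)
    # rigid rotation leaves arc-length pseudotime intact
    theta <- 1.1
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    r <- pseudotimeConservation(
        list(b1 = line), line %*% rot + 3, rep("b1", 150)
    )
    expect_gt(r[["b1"]], 0.999)
})

test_that("pseudotime survives mean-shift integration of a noisy S-curve", {
    withr::with_seed(61L, {
        t1 <- runif(150)
        t2 <- runif(150)
        sCurve <- function(t) cbind(sin(2 * t), 2 * t + cos(t))
        b1 <- sCurve(t1) + matrix(rnorm(300, sd = 0.05), 150, 2)
        b2 <- sCurve(t2) + matrix(rnorm(300, sd = 0.05), 150, 2) + 4
    })
    # integration = per-batch mean-shift removal
    integrated <- rbind(
        scale(b1, scale = FALSE), scale(b2, scale = FALSE)
    )
    r <- suppressWarnings(pseudotimeConservation(
        list(b1 = b1, b2 = b2), integrated,
        rep(c("b1", "b2"), each = 150)
    ))
    expect_gte(r[["b1"]], 0.9)
    expect_gte(r[["b2"]], 0.9)
})

test_that("overall scores average rank points within categories", {
    tab <- rbind(
        best = c(m1 = 0.9, m2 = 0.8, m3 = 0.95),
        mid = c(0.5, 0.6, 0.3),
        low = c(0.2, 0.3, 0.4),
        worst = c(0.1, 0.1, 0.1)
    )
    sc <- overallScore(tab, list(catA = c("m1", "m2"), catB = "m3"))
    # hand computation: m1, m2 rank best>mid>low>worst (points 4,3,2,1);
    # m3 ranks best>low>mid>worst (points 4,2,3,1)
    expect_equal(unname(sc[, "catA"]), c(4, 3, 2, 1))
    expect_equal(unname(sc[, "catB"]), c(4, 2, 3, 1))
    expect_equal(unname(sc[, "overall"]), rowMeans(cbind(
        c(4, 3, 2, 1), c(4, 3, 2, 1), c(4, 2, 3, 1)
    )), ignore_attr = TRUE)
    expect_equal(unname(sc["best", "overall"]), 4) # best on every metric

    # two methods, one dominant
    two <- rbind(a = c(x = 1, y = 1), b = c(0, 0))
    s2 <- overallScore(two, list(all = c("x", "y")))
    expect_equal(unname(s2[, "all"]), c(2, 1))

    # ties share mean points; NA metrics are skipped with warning
    tie <- rbind(a = c(x = 1, y = 0.5), b = c(1, 0.7))
    st <- overallScore(tie, list(all = c("x", "y")))
    expect_equal(unname(st[, "all"]), c((1.5 + 1) / 2, (1.5 + 2) / 2))
    withNA <- rbind(a = c(x = 1, y = NA), b = c(0, 1))
    expect_warning(sn <- overallScore(withNA, list(all = c("x", "y"))), "skipped")
    expect_equal(unname(sn[, "all"]), c(2, 1))
})
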