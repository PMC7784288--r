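# Fixtures shared across test files; everything is generated in code.

# Random Poisson count matrix with names, deterministic given seed.
toyCounts <- function(nGenes, nCells, seed = 1L, meanCount = 2) {
    withr::with_seed(seed, {
        m <- matrix(rpois(nGenes * nCells, meanCount), nGenes, nCells)
        dimnames(m) <- list(
            sprintf("g%03d", seq_len(nGenes)),
            sprintf("c%03d", seq_len(nCells))
        )
        m
    })
}

# Construct a SharedClusterPairs object directly from an edge table.
makePairs <- function(edges, threshold = 0.6) {
    if (!"passed" %in% colnames(edges)) {
        edges$passed <- edges$similarity > threshold
    }
    methods::new("SharedClusterPairs", edges = edges, threshold = threshold)
}

# Two-batch constant-offset toy: identical populations in both batches, a
# constant offset added to every feature of batch 2. The population signature
# is zero-sum (+3 on features 11:15, -3 on 16:20) so the biology axis is
# orthogonal to the all-ones batch offset direction.
makeShiftToy <- function(nPer = 60L, m = 20L, delta = 2, seed = 7L) {
    withr::with_seed(seed, {
        mkPop <- function(popSign, batchShift) {
            x <- matrix(rnorm(nPer * m, sd = 0.3), nPer, m)
            x[, 11:15] <- x[, 11:15] + 3 * popSign
            x[, 16:20] <- x[, 16:20] - 3 * popSign
            x + batchShift
        }
        x <- rbind(mkPop(0, 0), mkPop(1, 0), mkPop(0, delta), mkPop(1, delta))
        colnames(x) <- paste0("f", seq_len(m))
        rownames(x) <- paste0("cell", seq_len(nrow(x)))
        info <- data.frame(
            dataset = rep(c("b1", "b1", "b2", "b2"), each = nPer),
            cluster = rep(c(1L, 2L, 1L, 2L), each = nPer)
        )
        pairs <- makePairs(data.frame(
            dataset_i = "b1", cluster_p = c(1L, 2L),
            dataset_j = "b2", cluster_q = c(1L, 2L),
            overlap = 1, cosine = 1, similarity = 1
        ))
        list(
            x = x, info = info, pairs = pairs,
            batch = rep(c("b1", "b2"), each = 2L * nPer),
            pop = rep(c("p1", "p2", "p1", "p2"), each = nPer)
        )
    })
}

# Largest principal angle (radians) between the column spans of two
# orthonormal bases, via the sine formulation (numerically accurate for
# nearly identical subspaces, where acos of a singular value is not).
maxPrincipalAngle <- function(v1, v2) {
    q <- v2 - v1 %*% crossprod(v1, v2)
    asin(min(1, svd(q)$d[1]))
}

# Centroid of a subset of embedding rows.
centroid <- function(emb, idx) colMeans(emb[idx, , drop = FALSE])

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Brute-force pair-counting clustering metrics over all C(n,2) pairs.
bruteAgreement <- function(truth, pred) {
    n <- length(truth)
    sameT <- outer(truth, truth, "==")[upper.tri(diag(n))]
    sameP <- outer(pred, pred, "==")[upper.tri(diag(n))]
    a <- sum(sameT & sameP)
    b <- sum(sameT & !sameP)
    c_ <- sum(!sameT & sameP)
    d <- sum(!sameT & !sameP)
    tot <- a + b + c_ + d
    expected <- (a + b) * (a + c_) / tot
    denom <- ((a + b) + (a + c_)) / 2 - expected
    list(
        ari = if (denom == 0) as.numeric(a == expected) else (a - expected) / denom,
        jaccard = if (a + b + c_ == 0) 1 else a / (a + b + c_),
        purity = {
            tab <- table(truth, pred)
            sum(apply(tab, 2, max)) / n
        },
        nmi = {
            tab <- table(truth, pred) / n
            pa <- rowSums(tab)
            pb <- colSums(tab)
            h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
            mi <- 0
            for (i in seq_along(pa)) {
                for (j in seq_along(pb)) {
                    if (tab[i, j] > 0) {
                        mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
                    }
                }
            }
            if (h(pa) + h(pb) == 0) 1 else unname(2 * mi / (h(pa) + h(pb)))
        }
    )
}

# Quadratic-time reference silhouette (plain loops, no shared code).
bruteSilhouette <- function(emb, labels) {
    n <- nrow(emb)
    labels <- as.character(labels)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i] & seq_len(n) != i)
        if (length(own) == 0) {
            s[i] <- 0
            next
        }
        a <- mean(vapply(own, function(j) euclid(emb[i, ], emb[j, ]), 0))
        b <- Inf
        for (cl in setdiff(unique(labels), labels[i])) {
            oth <- which(labels == cl)
            b <- min(b, mean(vapply(
                oth,
                function(j) euclid(emb[i, ], emb[j, ]), 0
            )))
        }
        s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    mean(s)
}

# Brute-force POS by explicit pair enumeration.
brutePOS <- function(pt, gold) {
    n <- length(pt)
    conc <- 0
    disc <- 0
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            d1 <- sign(pt[i] - pt[j])
            d2 <- sign(gold[i] - gold[j])
            if (d1 * d2 > 0) conc <- conc + 1
            if (d1 * d2 < 0) disc <- disc + 1
        }
    }
    conc / (conc + disc)
}
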