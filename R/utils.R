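# Internal helpers shared across modules.

# k nearest neighbors by Euclidean distance, self excluded.
# Returns an n x k integer matrix of neighbor indices, row i sorted by
# increasing distance to point i. Dense blockwise computation; fine for the
# tens of thousands of cells this package targets per dataset.
.knnIndices <- function(x, k, blockSize = 1024L) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (n <= k) {
        stop("need more points than neighbors (n > k)")
    }
    sq <- rowSums(x^2)
    out <- matrix(0L, n, k)
    for (start in seq(1L, n, by = blockSize)) {
        idx <- start:min(start + blockSize - 1L, n)
        # squared distances block: |a|^2 + |b|^2 - 2 a.b
        d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
        for (r in seq_along(idx)) {
            i <- idx[r]
            di <- d2[r, ]
            di[i] <- Inf
            # partial ordering: order() is O(n log n), acceptable here
            out[i, ] <- order(di)[seq_len(k)]
        }
    }
    out
}

# Cosine similarity of two nonnegative vectors, clipped to [0, 1];
# zero vector on either side gives 0.
.cosine <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
        return(0)
    }
    min(1, max(0, sum(a * b) / (na * nb)))
}

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive order-invariant sub-seeds from unordered pair identities.
.stringHash <- function(s) {
    codes <- utf8ToInt(s)
    h <- 0
    m <- 2147483647 # 2^31 - 1
    for (c in codes) {
        h <- (h * 31 + c) %% m
    }
    as.integer(h)
}

# Sub-seed derived from a master seed and a character tag; stays below 2^31.
.deriveSeed <- function(seed, tag) {
    as.integer((as.numeric(seed) + .stringHash(tag)) %% 2147483647)
}

# Column centering that keeps dimnames.
.centerColumns <- function(x, center) {
    sweep(as.matrix(x), 2L, center, "-")
}

.checkBinaryLabels <- function(x, n, what) {
    if (length(x) != n) {
        stop(sprintf("'%s' must have one entry per cell", what))
    }
    x
}
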