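#' Quality-control filtering of a count matrix
#'
#' Removes features detected in fewer than \code{minCells} cells, then cells
#' with fewer than \code{minFeatures} detected features (single pass, features
#' first). The defaults are the conventional scRNA-seq cutoffs: a feature must
#' be seen in at least 3 cells and a cell must express at least 200 features.
#'
#' @param counts nonnegative matrix (dense or sparse), features x cells, with
#'   unique row and column names.
#' @param minCells minimum number of cells a retained feature is detected in.
#' @param minFeatures minimum number of detected features in a retained cell.
#' @return The filtered matrix, same class as the input.
#' @export
filterQC <- function(counts, minCells = 3L, minFeatures = 200L) {
    .checkCountMatrix(counts)
    keepFeature <- Matrix::rowSums(counts > 0) >= minCells
    counts <- counts[keepFeature, , drop = FALSE]
    keepCell <- Matrix::colSums(counts > 0) >= minFeatures
    counts <- counts[, keepCell, drop = FALSE]
    if (nrow(counts) == 0L || ncol(counts) == 0L) {
        stop("no cells/features survive QC")
    }
    counts
}

#' Log-normalize a count matrix
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' \code{scaleFactor} and transformed with \code{log(1 + x)} (natural log).
#'
#' @param counts nonnegative features x cells matrix; every cell total must be
#'   positive.
#' @param scaleFactor library-size target, 10,000 by default.
#' @return A dense features x cells matrix of log-normalized values.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
    .checkCountMatrix(counts)
    stopifnot(scaleFactor > 0)
    totals <- Matrix::colSums(counts)
    if (any(totals <= 0)) {
        bad <- colnames(counts)[totals <= 0]
        if (is.null(bad)) bad <- which(totals <= 0)
        stop(
            "cells with zero total counts cannot be normalized: ",
            paste(utils::head(bad, 5L), collapse = ", ")
        )
    }
    out <- as.matrix(counts)
    out <- log1p(sweep(out, 2L, totals, "/") * scaleFactor)
    dimnames(out) <- dimnames(counts)
    out
}

#' Select highly variable genes by binned Fano factor
#'
#' Computes the per-gene mean and Fano factor (variance / mean) on the
#' log-normalized matrix, bins genes into \code{nBins} equal-count groups by
#' mean expression, z-scores the Fano factors within each bin, and keeps genes
#' whose normalized Fano factor exceeds \code{fanoThreshold} and whose mean
#' exceeds \code{meanThreshold}. Genes with zero mean are excluded up front.
#'
#' @param norm log-normalized features x cells matrix.
#' @param nBins number of equal-count mean-expression bins (default 20).
#' @param fanoThreshold minimum within-bin z-scored Fano factor (default 0.05).
#' @param meanThreshold minimum mean expression (default 0.01).
#' @return Character vector of selected feature ids, sorted by decreasing
#'   normalized Fano factor.
#' @export
selectHVG <- function(norm, nBins = 20L, fanoThreshold = 0.05,
                      meanThreshold = 0.01) {
    norm <- as.matrix(norm)
    if (is.null(rownames(norm))) {
        stop("'norm' must have feature names as row names")
    }
    mu <- rowMeans(norm)
    keep <- mu > 0
    mu <- mu[keep]
    v <- apply(norm[keep, , drop = FALSE], 1L, stats::var)
    fano <- v / mu
    n <- length(mu)
    if (n == 0L) {
        return(character(0))
    }
    if (n < nBins) {
        warning("fewer genes than bins; reducing bin count to ", n)
        nBins <- n
    }
    # equal-count bins by mean expression; ties broken by input gene order
    r <- rank(mu, ties.method = "first")
    bin <- ceiling(r * nBins / n)
    z <- fano
    for (b in unique(bin)) {
        i <- bin == b
        s <- stats::sd(fano[i])
        m <- mean(fano[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (fano[i] - m) / s
    }
    sel <- z > fanoThreshold & mu > meanThreshold
    ids <- names(mu)[sel]
    ids[order(z[sel], decreasing = TRUE)]
}

#' Gene activity scores from a peaks-by-cells accessibility matrix
#'
#' Converts scATAC peak counts to gene-level activity: every peak whose
#' midpoint falls within \code{window} bp of a gene's transcription start site
#' contributes its counts weighted by \code{exp(-distance / decayScale)}.
#' Genes with no peak in the window get all-zero rows.
#'
#' @param peakCounts nonnegative peaks x cells matrix; row names are peak ids.
#' @param peakRanges a \link[GenomicRanges]{GRanges} of the peak intervals
#'   (names matching the peak ids), or the path of a BED file (0-based
#'   half-open) whose rows are in the same order as \code{rownames(peakCounts)}.
#' @param tss data.frame with columns \code{gene}, \code{chrom}, \code{tss}
#'   (position), \code{strand}; one row per gene.
#' @param window half-width of the regulatory window around the TSS (bp).
#' @param decayScale exponential decay length scale (bp).
#' @return Dense genes x cells matrix of activity scores.
#' @export
geneActivity <- function(peakCounts, peakRanges, tss, window = 5e4,
                         decayScale = 5e3) {
    .checkCountMatrix(peakCounts)
    peakIds <- rownames(peakCounts)
    if (is.character(peakRanges) && length(peakRanges) == 1L) {
        if (!requireNamespace("rtracklayer", quietly = TRUE)) {
            stop("reading BED paths requires the rtracklayer package")
        }
        peakRanges <- rtracklayer::import(peakRanges, format = "BED")
        if (length(peakRanges) != length(peakIds)) {
            stop("BED file must have one interval per peak row")
        }
        names(peakRanges) <- peakIds
    }
    stopifnot(methods::is(peakRanges, "GRanges"))
    missing <- setdiff(peakIds, names(peakRanges))
    if (length(missing)) {
        stop(
            "peaks without coordinates: ",
            paste(utils::head(missing, 10L), collapse = ", ")
        )
    }
    peakRanges <- peakRanges[peakIds]
    stopifnot(all(c("gene", "chrom", "tss", "strand") %in% colnames(tss)))
    mid <- (GenomicRanges::start(peakRanges) +
        GenomicRanges::end(peakRanges) - 1) / 2
    tssGr <- GenomicRanges::GRanges(
        seqnames = tss$chrom,
        ranges = IRanges::IRanges(start = tss$tss, width = 1L)
    )
    midGr <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(peakRanges),
        ranges = IRanges::IRanges(start = round(mid), width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(
        tssGr, midGr,
        maxgap = as.integer(window)
    )
    gi <- S4Vectors::queryHits(hits)
    pi <- S4Vectors::subjectHits(hits)
    d <- abs(mid[pi] - tss$tss[gi])
    inWin <- d <= window
    gi <- gi[inWin]
    pi <- pi[inWin]
    w <- exp(-d[inWin] / decayScale)
    wMat <- Matrix::sparseMatrix(
        i = gi, j = pi, x = w,
        dims = c(nrow(tss), nrow(peakCounts))
    )
    out <- as.matrix(wMat %*% peakCounts)
    rownames(out) <- tss$gene
    colnames(out) <- colnames(peakCounts)
    out
}

#' Common feature space across datasets
#'
#' Builds the shared feature set (the union of the per-dataset HVG lists,
#' intersected with the features present in every dataset) and returns each
#' dataset restricted to it, as a cells x features matrix with identical
#' column order everywhere — the layout the correction step works in.
#'
#' @param normList named list (>= 2) of log-normalized features x cells
#'   matrices; names are the batch ids.
#' @param hvgList list of HVG character vectors, one per dataset.
#' @return Named list of cells x m matrices over the identical feature set.
#' @export
intersectFeatures <- function(normList, hvgList) {
    if (length(normList) < 2L) {
        stop("need at least two datasets")
    }
    if (length(hvgList) != length(normList)) {
        stop("one HVG list per dataset required")
    }
    present <- Reduce(intersect, lapply(normList, rownames))
    # sorted so the column order never depends on the dataset input order
    shared <- sort(intersect(unique(unlist(hvgList)), present))
    if (length(shared) == 0L) {
        stop("no shared features: HVG union does not intersect all datasets")
    }
    lapply(normList, function(m) t(as.matrix(m[shared, , drop = FALSE])))
}

#' Read a MatrixMarket dataset
#'
#' Reads the conventional triplet of \code{matrix.mtx} (features x cells),
#' \code{features.tsv} and \code{barcodes.tsv} from a directory.
#'
#' @param dir directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return Sparse features x cells matrix with dimnames.
#' @export
readMTXDataset <- function(dir) {
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    feats <- utils::read.table(file.path(dir, "features.tsv"),
        sep = "\t",
        stringsAsFactors = FALSE
    )[, 1L]
    cells <- utils::read.table(file.path(dir, "barcodes.tsv"),
        sep = "\t",
        stringsAsFactors = FALSE
    )[, 1L]
    dimnames(m) <- list(feats, cells)
    methods::as(m, "CsparseMatrix")
}

#' Read a dense CSV dataset
#'
#' @param path CSV file with cells as rows and features as columns (first
#'   column = cell ids, header = feature ids), matching the package's export
#'   convention.
#' @return Dense features x cells matrix.
#' @export
readCSVDataset <- function(path) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    t(as.matrix(df))
}

.checkCountMatrix <- function(x) {
    if (is.null(dim(x)) || any(dim(x) == 0L)) {
        stop("input must be a non-empty matrix")
    }
    if (min(x) < 0) {
        stop("values must be nonnegative")
    }
    if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
        stop("duplicate feature or cell ids")
    }
    invisible(TRUE)
}
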