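#' Configuration for the multi-batch count simulator
#'
#' Validates and assembles the generative settings for
#' \code{\link{simulateCounts}} / \code{\link{simulateTrajectory}}: a
#' gamma-Poisson count model with multiplicative group (cell-population) and
#' batch factors. Gene base means are Gamma(shape, rate); each group
#' multiplies its planted DE genes by a fold-change; each batch multiplies
#' every gene by a lognormal factor; per-cell library-size factors are
#' lognormal(0, 0.2); counts are Poisson.
#'
#' @param nGenes number of genes.
#' @param batches named list; each element is a list with \code{nCells} and
#'   \code{proportions} (named vector over group names, summing to 1). For
#'   trajectory scenarios \code{proportions} is ignored.
#' @param groups named list; each element a list with \code{deFrac} (fraction
#'   of genes differentially expressed in that group) and \code{foldChange}
#'   (> 0).
#' @param batchEffect list with \code{location} and \code{scale} of the
#'   per-batch lognormal gene factors; \code{scale} may be a vector (one per
#'   batch). Scale 0 means no batch effect.
#' @param trajectory NULL, or a list with \code{deFrac} and \code{foldChange}
#'   describing the two endpoint expression programs of a continuous path.
#' @param libSizeScale sdlog of the per-cell library-size factor.
#' @param gammaShape,gammaRate parameters of the gene base-mean distribution.
#' @param seed mandatory integer seed.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nGenes, batches, groups, batchEffect = list(
                          location = 0, scale = 0.25
                      ),
                      trajectory = NULL, libSizeScale = 0.2,
                      gammaShape = 0.6, gammaRate = 0.3, seed) {
    if (missing(seed)) {
        stop("a seed is mandatory")
    }
    stopifnot(nGenes >= 1L, length(batches) >= 1L)
    if (is.null(names(batches))) {
        names(batches) <- paste0("batch", seq_along(batches))
    }
    for (b in batches) {
        stopifnot(b$nCells >= 1L)
        if (is.null(trajectory)) {
            stopifnot(abs(sum(b$proportions) - 1) < 1e-8)
            if (!all(names(b$proportions) %in% names(groups))) {
                stop("batch proportions refer to unknown groups")
            }
        }
    }
    for (g in groups) {
        stopifnot(g$foldChange > 0, g$deFrac >= 0, g$deFrac <= 1)
    }
    cfg <- list(
        nGenes = as.integer(nGenes), batches = batches, groups = groups,
        batchEffect = batchEffect, trajectory = trajectory,
        libSizeScale = libSizeScale, gammaShape = gammaShape,
        gammaRate = gammaRate, seed = as.integer(seed)
    )
    class(cfg) <- "SimConfig"
    cfg
}

# Shared generative state: gene base means, disjoint DE gene sets and their
# multiplicative factors per group, per-batch gene factors.
.simState <- function(cfg) {
    nGenes <- cfg$nGenes
    baseMean <- stats::rgamma(nGenes, shape = cfg$gammaShape, rate = cfg$gammaRate)
    geneIds <- sprintf("gene%04d", seq_len(nGenes))
    groupNames <- names(cfg$groups)
    nDe <- vapply(cfg$groups, function(g) round(g$deFrac * nGenes), numeric(1))
    pool <- sample(nGenes)
    deSets <- list()
    offset <- 0
    for (i in seq_along(cfg$groups)) {
        take <- nDe[i]
        if (offset + take <= nGenes) {
            deSets[[groupNames[i]]] <- pool[offset + seq_len(take)]
            offset <- offset + take
        } else {
            deSets[[groupNames[i]]] <- sample(nGenes, take)
        }
    }
    groupFactor <- sapply(groupNames, function(g) {
        f <- rep(1, nGenes)
        f[deSets[[g]]] <- cfg$groups[[g]]$foldChange
        f
    })
    scales <- rep(cfg$batchEffect$scale, length.out = length(cfg$batches))
    batchFactor <- sapply(seq_along(cfg$batches), function(b) {
        if (scales[b] == 0) {
            rep(1, nGenes)
        } else {
            stats::rlnorm(nGenes, cfg$batchEffect$location, scales[b])
        }
    })
    colnames(batchFactor) <- names(cfg$batches)
    list(
        baseMean = baseMean, geneIds = geneIds, deSets = deSets,
        groupFactor = groupFactor, batchFactor = batchFactor
    )
}

#' Simulate multi-batch single-cell counts with ground truth
#'
#' Draws gamma-Poisson counts for every batch of the configuration:
#' \code{counts ~ Poisson(libFactor * baseMean * groupFactor * batchFactor)}.
#' Fully deterministic given the config seed.
#'
#' @param cfg a \code{\link{simConfig}} (discrete-group scenario).
#' @return List with \code{datasets} (named list of genes x cells count
#'   matrices, one per batch) and \code{truth} (group and batch label per
#'   cell, DE gene ids per group, the batch factor matrix).
#' @export
simulateCounts <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"), is.null(cfg$trajectory))
    withr::with_seed(cfg$seed, {
        st <- .simState(cfg)
        datasets <- list()
        group <- list()
        for (b in names(cfg$batches)) {
            bc <- cfg$batches[[b]]
            nPer <- .splitCells(bc$nCells, bc$proportions)
            cellGroup <- rep(names(nPer), nPer)
            lib <- stats::rlnorm(bc$nCells, 0, cfg$libSizeScale)
            mu <- st$baseMean * st$batchFactor[, b]
            lam <- mu * st$groupFactor[, cellGroup, drop = FALSE]
            lam <- sweep(lam, 2L, lib, "*")
            counts <- matrix(
                stats::rpois(length(lam), as.vector(lam)),
                nrow = cfg$nGenes,
                dimnames = list(
                    st$geneIds,
                    paste0(b, "_cell", seq_len(bc$nCells))
                )
            )
            datasets[[b]] <- counts
            group[[b]] <- stats::setNames(cellGroup, colnames(counts))
        }
        list(
            datasets = datasets,
            truth = list(
                group = group,
                batch = rep(names(cfg$batches), vapply(
                    cfg$batches, `[[`, numeric(1), "nCells"
                )),
                deGenes = lapply(st$deSets, function(i) st$geneIds[i]),
                batchFactor = st$batchFactor,
                pseudotime = NULL
            )
        )
    })
}

#' Simulate a continuous trajectory across batches
#'
#' Each cell carries a latent time t ~ Uniform(0, 1); gene means interpolate
#' log-linearly between two endpoint programs (each an independent set of
#' amplified genes), batch and library-size factors apply as in
#' \code{\link{simulateCounts}}, and t is recorded as the gold-standard
#' pseudotime.
#'
#' @param cfg a \code{\link{simConfig}} with a \code{trajectory} block.
#' @return As \code{\link{simulateCounts}}, with \code{truth$pseudotime} a
#'   named list of per-batch latent times.
#' @export
simulateTrajectory <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"), !is.null(cfg$trajectory))
    tr <- cfg$trajectory
    withr::with_seed(cfg$seed, {
        nGenes <- cfg$nGenes
        baseMean <- stats::rgamma(nGenes, cfg$gammaShape, cfg$gammaRate)
        geneIds <- sprintf("gene%04d", seq_len(nGenes))
        nDe <- round(tr$deFrac * nGenes)
        pool <- sample(nGenes, 2 * nDe)
        progA <- rep(1, nGenes)
        progB <- rep(1, nGenes)
        progA[pool[seq_len(nDe)]] <- tr$foldChange
        progB[pool[nDe + seq_len(nDe)]] <- tr$foldChange
        scales <- rep(cfg$batchEffect$scale, length.out = length(cfg$batches))
        datasets <- list()
        pseudotime <- list()
        for (bi in seq_along(cfg$batches)) {
            b <- names(cfg$batches)[bi]
            nCells <- cfg$batches[[b]]$nCells
            t <- stats::runif(nCells)
            lib <- stats::rlnorm(nCells, 0, cfg$libSizeScale)
            bf <- if (scales[bi] == 0) {
                rep(1, nGenes)
            } else {
                stats::rlnorm(nGenes, cfg$batchEffect$location, scales[bi])
            }
            # log-linear interpolation between the endpoint programs
            lam <- exp(outer(log(progA), 1 - t) + outer(log(progB), t)) *
                (baseMean * bf) * rep(lib, each = nGenes)
            counts <- matrix(
                stats::rpois(length(lam), as.vector(lam)),
                nrow = nGenes,
                dimnames = list(geneIds, paste0(b, "_cell", seq_len(nCells)))
            )
            datasets[[b]] <- counts
            pseudotime[[b]] <- stats::setNames(t, colnames(counts))
        }
        list(
            datasets = datasets,
            truth = list(
                group = NULL,
                batch = rep(names(cfg$batches), vapply(
                    cfg$batches, `[[`, numeric(1), "nCells"
                )),
                deGenes = list(
                    start = geneIds[pool[seq_len(nDe)]],
                    end = geneIds[pool[nDe + seq_len(nDe)]]
                ),
                pseudotime = pseudotime
            )
        )
    })
}

#' Scenario presets for the simulator
#'
#' Six reduced-scale scenario-shaped configurations covering the standard
#' integration stress cases: (s1) two batches with identical subpopulation
#' composition; (s2) two batches with imbalanced compositions, six groups in
#' batch 1 versus four in batch 2, 1,500 cells in total; (s3) three batches
#' with imbalanced compositions (4/5/3 groups); (s4) two batches along a
#' continuous trajectory; (s5) six batches; (s6) sixteen nested sub-batches
#' (four sets of four, with set-level times sub-batch-level factors).
#'
#' @param name one of "s1" .. "s6".
#' @param seed integer seed stored in the config (default 1).
#' @return A \code{\link{simConfig}}.
#' @examples
#' sim <- simulateFromConfig(simPreset("s1", seed = 1L))
#' names(sim$datasets)
#' table(sim$truth$group$batch1)
#' @export
simPreset <- function(name, seed = 1L) {
    eq <- function(groups) {
        stats::setNames(
            rep(1 / length(groups), length(groups)),
            groups
        )
    }
    grp <- function(groups, deFrac = 0.06, fc = 4) {
        stats::setNames(
            lapply(groups, function(g) list(deFrac = deFrac, foldChange = fc)),
            groups
        )
    }
    switch(name,
        s1 = simConfig(
            nGenes = 1200L,
            batches = list(
                batch1 = list(nCells = 400L, proportions = eq(paste0("g", 1:4))),
                batch2 = list(nCells = 400L, proportions = eq(paste0("g", 1:4)))
            ),
            groups = grp(paste0("g", 1:4)),
            batchEffect = list(location = 0, scale = 0.25),
            seed = seed
        ),
        s2 = simConfig(
            nGenes = 1200L,
            batches = list(
                batch1 = list(nCells = 900L, proportions = eq(paste0("g", 1:6))),
                batch2 = list(nCells = 600L, proportions = eq(paste0("g", 1:4)))
            ),
            groups = grp(paste0("g", 1:6)),
            batchEffect = list(location = 0, scale = 0.25),
            seed = seed
        ),
        s3 = simConfig(
            nGenes = 1200L,
            batches = list(
                batch1 = list(nCells = 500L, proportions = eq(paste0("g", 1:4))),
                batch2 = list(nCells = 500L, proportions = eq(paste0("g", 1:5))),
                batch3 = list(nCells = 400L, proportions = eq(paste0("g", 1:3)))
            ),
            groups = grp(paste0("g", 1:5)),
            batchEffect = list(location = 0, scale = 0.25),
            seed = seed
        ),
        s4 = simConfig(
            nGenes = 1000L,
            batches = list(
                batch1 = list(nCells = 350L),
                batch2 = list(nCells = 350L)
            ),
            groups = list(path = list(deFrac = 0.1, foldChange = 5)),
            batchEffect = list(location = 0, scale = 0.3),
            trajectory = list(deFrac = 0.1, foldChange = 5),
            seed = seed
        ),
        s5 = simConfig(
            nGenes = 1200L,
            batches = stats::setNames(
                rep(list(list(nCells = 500L, proportions = eq(paste0("g", 1:5)))), 6L),
                paste0("batch", 1:6)
            ),
            groups = grp(paste0("g", 1:5)),
            batchEffect = list(location = 0, scale = 0.25),
            seed = seed
        ),
        s6 = {
            sets <- paste0("set", 1:4)
            subs <- unlist(lapply(sets, function(s) paste0(s, ".sub", 1:4)))
            cfg <- simConfig(
                nGenes = 1200L,
                batches = stats::setNames(
                    rep(list(list(nCells = 200L, proportions = eq(paste0("g", 1:4)))), 16L),
                    subs
                ),
                groups = grp(paste0("g", 1:4)),
                # nested: set-level scale 0.2 times sub-batch-level scale 0.1,
                # realised through per-sub-batch composed factors below
                batchEffect = list(location = 0, scale = 0.1),
                seed = seed
            )
            cfg$nested <- list(sets = sets, setScale = 0.2)
            cfg
        },
        stop("unknown preset: ", name)
    )
}

#' Simulate from a preset, composing nested batch factors where defined
#'
#' Dispatches to \code{\link{simulateCounts}} or
#' \code{\link{simulateTrajectory}} and, for the nested sub-batch scenario,
#' multiplies every sub-batch's gene factors by its set-level factor.
#'
#' @param cfg a \code{\link{simConfig}}, usually from \code{\link{simPreset}}.
#' @return As \code{\link{simulateCounts}}.
#' @export
simulateFromConfig <- function(cfg) {
    if (!is.null(cfg$trajectory)) {
        return(simulateTrajectory(cfg))
    }
    if (is.null(cfg$nested)) {
        return(simulateCounts(cfg))
    }
    # nested sub-batches: a set-level gene factor shared by the four
    # sub-batches of a set, composed with each sub-batch's own factor
    sim <- withr::with_seed(cfg$seed + 7L, {
        setFactor <- sapply(cfg$nested$sets, function(s) {
            stats::rlnorm(cfg$nGenes, 0, cfg$nested$setScale)
        })
        base <- simulateCounts(cfg)
        for (b in names(base$datasets)) {
            s <- sub("\\.sub[0-9]+$", "", b)
            f <- setFactor[, s]
            counts <- base$datasets[[b]]
            # compose the set-level factor by binomial thinning / Poisson
            # boosting, preserving integer counts
            boosted <- matrix(
                stats::rpois(length(counts), as.vector(counts * f)),
                nrow = nrow(counts), dimnames = dimnames(counts)
            )
            base$datasets[[b]] <- boosted
            base$truth$batchFactor[, b] <- base$truth$batchFactor[, b] * f
        }
        base
    })
    sim
}

# integer cell counts per group honoring the proportions
.splitCells <- function(nCells, proportions) {
    nPer <- floor(proportions * nCells)
    rem <- nCells - sum(nPer)
    if (rem > 0) {
        add <- order(proportions * nCells - nPer, decreasing = TRUE)[seq_len(rem)]
        nPer[add] <- nPer[add] + 1
    }
    nPer
}
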