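# scBatchAlign

Batch-effect correction for multi-dataset single-cell genomics that removes
technical variation while keeping dataset-specific biology.

## The problem

When single-cell RNA-seq or ATAC-seq datasets from different experiments,
conditions or platforms are analyzed jointly, technical variation (batch
effects) mixes with the biological variation of interest. Most integration
methods align datasets by forcing them to overlap, which can erase
populations that genuinely exist in only one condition — a control-specific
or perturbation-specific cell type gets merged into its nearest neighbor.
scBatchAlign takes the opposite route: it first works out *which* parts of
the data are comparable across datasets, declares only their differences to
be technical, and subtracts exactly that.

## The method

For datasets with feature matrices stacked as X̂ (confident cells × m
features) the pipeline is:

1. **Per-dataset consensus clustering.** A shared nearest neighbor (SNN)
   graph is built from the top 40 PCs (k = 20 neighbors; edge weight
   |NN(i) ∩ NN(j)|/k). Leiden clustering runs at resolutions 0.1–0.5, the
   co-clustering frequencies form a consensus matrix, the cluster number is
   the count of singular values holding > 1 % of the spectral mass, and an
   average-linkage cut of (1 − consensus) gives the putative clusters.
2. **Confident cells.** In each cluster, cells whose average SNN similarity
   to their cluster mates exceeds the cluster's third quartile (Q3).
3. **Shared clusters.** For every cluster pair across datasets, markers are
   found on confident cells with a two-part (hurdle) likelihood-ratio test
   (p < 0.05, ln fold-change > 0.25, expressed fraction > 25 %). Pair
   similarity = ½·(marker overlap s/min(n₁,n₂) + cosine similarity of mean
   marker expression); pairs with similarity > T = 0.6 are shared.
4. **Correction vectors.** Shared-pair cells are matched one-to-one into a
   signed indicator matrix Y, so that rows of YᵀX̂ are paired difference
   vectors. The correction vectors V solve

   max_V  VᵀX̂ᵀX̂V − λ·VᵀX̂ᵀYYᵀX̂V,   ‖V_,i‖₂² ≤ 1,

   i.e. the eigenvectors of X̂ᵀX̂ − λX̂ᵀYYᵀX̂ with positive eigenvalues
   (λ = 10 by default). The technical-variation ratio
   R = tr(VᵀX̂ᵀYYᵀX̂V) / (tr(VᵀX̂ᵀYYᵀX̂V) + tr(VᵀX̂ᵀX̂V)) reports how much
   technical signal remains in the embedding.
5. **Shared embedding.** All cells — confident or not, matched or
   dataset-specific — are projected: L = XV. The stored basis can also embed
   datasets that arrive later (`projectNewDataset`).

The package additionally ships the evaluation metrics used to benchmark such
integrations (NMI/ARI/Jaccard/purity, silhouette, normalized LISI and the
LISI-derived F1, the specificity score for condition-specific populations,
the pseudotime ordering score POS with Kendall's τ, principal-curve
pseudotime conservation, rank-based overall scores) and a gamma-Poisson
simulator of multi-batch count data with planted ground truth.

## Worked example

Integrate the bundled imbalanced scenario — two batches, six subpopulations
in batch 1 but only four in batch 2, 1,500 cells:

```r
library(scBatchAlign)

sim <- simulateFromConfig(simPreset("s2", seed = 1L))
res <- runIntegration(sim$datasets, integrationConfig(seed = 1L))
res
#> IntegrationResult: 1500 cells from 2 batches embedded in 40 dimensions
#>   shared cluster pairs: 4 ; technical-variation ratio 0.00506

sharedPairs(res)[, c("dataset_i", "cluster_p", "dataset_j", "cluster_q",
                     "similarity")]
#>    dataset_i cluster_p dataset_j cluster_q similarity
#> 1     batch1         1    batch2         1  0.9652843
#> 6     batch1         2    batch2         2  0.9803556
#> 11    batch1         3    batch2         3  0.9882004
#> 16    batch1         4    batch2         4  0.9532579
```

Exactly the four subpopulations present in both batches are matched
(similarity ≈ 0.95–0.99); the two batch-1-specific groups match nothing and
keep their own territory in the embedding:

```r
emb   <- cellEmbedding(res)
truth <- unlist(sim$truth$group, use.names = FALSE)
specificityScore(emb, truth %in% c("g5", "g6"))
#> [1] 1
silhouetteScore(emb, truth)
#> [1] 0.512
```

A specificity score of 1 means no batch-1-specific cell has any foreign
nearest neighbors — the populations absent from batch 2 were not forced
into an alignment — while the positive type silhouette shows the shared
populations are cleanly separated after correction. The technical-variation
ratio near 0.005 says almost no batch signal survives in the embedding.

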