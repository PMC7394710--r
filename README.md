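# morphoclust

Unsupervised species delimitation from morphometric character tables.

Taxonomists working on a species complex — closely related taxa whose
measurements overlap — usually ordinate their data (PCA, nMDS) and judge
cluster boundaries by eye, guided by the very labels under scrutiny.
`morphoclust` takes the unsupervised route: it discovers clusters of
individuals directly from the measurements by **spectral clustering**,
selects the number of clusters with the **eigengap heuristic**, and then
explains each cluster by the morphological characters that define it.
Taxonomist labels are used only afterwards, to quantify agreement.

## The method

For `N` individuals measured on `d` standardized continuous characters,
pairwise similarity is the RBF kernel

    S_ij = exp( -(gamma / d) * || x_i - x_j ||^2 ),

and clustering operates on the normalized symmetric graph Laplacian
`L = I - D^(-1/2) S D^(-1/2)` (`D_ii = sum_j S_ij`): the eigenvectors of
the `K` smallest eigenvalues, row-renormalized, are partitioned by
k-means (100 seeded restarts, lowest within-cluster sum of squares
wins). Sweeping `gamma` (default 0.05–1.0 in steps of 0.05) and `K`
(default 2–20) and scoring each `K` by its eigengap
`lambda_{K+1} - lambda_K` yields consensus candidate cluster counts.
Discovered clusters are characterized three ways: mutual information
between each character and the assignment (nearest-neighbour estimator
for continuous characters vs discrete labels), Pearson correlation
between characters and Laplacian eigenvectors, and cluster-versus-rest
Welch t-tests. PCA and nMDS (Gower distances, Kruskal stress-1) with
k-means on the first two dimensions are included as the traditional
baselines, and a seeded generator produces synthetic species complexes
for benchmarking. See the vignette
(`vignettes/spectral-species-delimitation.Rmd`) for the full model,
parameter meanings and design choices.

## Worked example

A synthetic two-complex study (10 taxa, 93 individuals, 16 characters of
which 8 informative, one hybrid taxon) stands in for an unpublished
measurement table:

```r
library(morphoclust)

sim  <- simulate_species_complex(two_complex_preset(seed = 42))
m    <- standardize(sim$matrix)
sweep <- spectral_sweep(m, sweep_config(seed = 42))
peaks <- detect_eigengap_peaks(sweep)
peaks
#> eigengap selection report
#> consensus K: 4
#> 0/20 gamma values excluded (no prominent peak)

scores <- validate_sweep(sweep, sim$matrix$ground_truth)
best   <- scores[scores$K %in% peaks$consensus, ]
best[which.max(best$nmi), ]
#>   gamma K      nmi      rand adjusted_rand
#> 3  0.05 4 0.438135 0.7884525     0.3013187
```

The eigengap nominates `K = 4` coarse clusters: with centroids only 4
within-taxon SDs apart, several taxa coalesce — the situation the method
is designed to expose, and the NMI of 0.44 against the 10 planted labels
quantifies exactly that partial agreement. The characters driving the
clusters are recovered cleanly — all top-ranked characters are planted
informative ones:

```r
assignment <- sweep$assignments[[1]][["4"]]
head(mi_character_cluster(m, assignment, seed = 42), 5)
#>   character        mi rank clipped constant
#> 1    inf_08 0.5933509    1   FALSE    FALSE
#> 2    inf_05 0.5039791    2   FALSE    FALSE
#> 3    inf_06 0.3976136    3   FALSE    FALSE
#> 4    inf_04 0.2609867    4   FALSE    FALSE
#> 5    inf_01 0.2518610    5   FALSE    FALSE
```

The ordination baselines on the same data, for comparison:

```r
pca <- pca_ordination(m)
sum(pca$all_variance_fractions[1:2])   # 0.285 — PC1+PC2 variance
nmds_ordination(gower_distance(sim$matrix), seed = 42)$stress  # 0.268
```

`run_pipeline(run_config(...))` chains all stages (preprocessing →
sweep → peak detection → validation → character analysis) and writes
every table plus a manifest that reproduces the run byte-for-byte
(`run_from_manifest()`). A command-line wrapper with verbs `generate`,
`cluster`, `validate`, `characters`, `ordinate` and `run` is installed at
`inst/cli/morphoclust.R`.

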