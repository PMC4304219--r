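# camodi

Gene **module discovery** from expression data: find clusters of genes whose
expression across samples is well approximated by one shared sparse linear
combination of a few **regulator (driver) genes** — e.g. transcription
factors — together with the full evaluation protocol used to judge such
module sets (adjusted R², bootstrap consistency, homogeneity) and a
synthetic planted-module generator for verification.

The intended user is a computational biologist with a genes × samples
expression matrix (tumor cohorts are the motivating case) and a list of
candidate regulators, who wants interpretable modules: each module
`M = {G, R}` pairs member genes `G` with regulators `R` and coefficients
`α`, such that for every gene `i ∈ G` and sample `k`

```
ŝ_i(k) = Σ_{j ∈ R} α_j s_j(k)
```

— one shared prediction for all member genes.

## The algorithm

An iterative procedure built from four steps:

1. **Gene sparsification.** Each gene is expressed as p-sparse linear
   combinations of the regulators for p = 1..C₁, by walking the elastic-net
   regularization path (fixed L₂ penalty, decreasing L₁ penalty) and
   recording the coefficient vector at each sparsity level.
2. **K-means clustering** of the S₁-sparse coefficient vectors (not the raw
   expression), so genes cluster when the same few regulators describe them.
   S₁ is the *initial sparsity*.
3. **Centroid sparsification.** Each cluster's expression centroid (mean of
   the members' original expression) is re-sparsified over the regulators,
   with the sparsity (≤ C₂) selected by 10-fold cross-validation over the
   cluster's *genes*; the cross-validated R² ranks the clusters.
4. **Cluster filtering.** The top P% of clusters are retained, plus any
   cluster with cross-validated R² above `r_thresh` and between `n_min` and
   `n_max` genes. Retained clusters become final modules; the remaining
   genes re-enter step 1 with S₁ incremented by 2 (capped at C₁).

Module quality is evaluated on random 70/30 train-test "bootstraps" with:

- **R² / adjusted R̄²** — residual energy of the shared prediction relative
  to the module genes' total energy; `R̄² = R² − (1−R²)·|R|/(m−|R|−1)`
  penalizes regulator count `|R|` relative to sample count `m`;
- **consistency S** — mean best-match average Jaccard similarity
  `(J(G₁,G₂)+J(R₁,R₂))/2` of module sets across bootstrap pairs;
- **homogeneity H** — mean pairwise Pearson correlation of member genes,
  averaged over modules;
- the **reporting filter** — keep modules of 5–1000 genes, rank by R̄²,
  retain the best modules covering ≥ 80% of the genes.

## Worked example

```r
library(camodi)

# a planted world: 4 modules x 20 genes over 20 regulators, 30 background
# genes, noise sd 0.2, 120 samples
sim <- generate_planted(planted_design(n_modules = 4, n_background_genes = 30,
                                       n_regulators = 20, m_samples = 120,
                                       seed = 7))
sim$x
#> ExpressionMatrix: 130 genes x 120 samples (20 regulators flagged)

cfg <- camodi_config(c1 = 4, c2 = 4, k = 6, var_fraction = 1, base_seed = 7)
res <- run_bootstraps(sim$x, cfg, 2)
res[[1]]$iterations
#>   iteration s1 clusters_formed clusters_candidate clusters_retained genes_remaining
#> 1         1  1               6                  4                 3              68
#> 2         2  3               3                  3                 1              48
#> 3         3  4               2                  2                 1               5

res[[1]]$modules[[1]]
#> Module it1_c1: 20 genes, 3 regulators (cv_r2 = 0.989, adj_r2_test = 0.990)

evaluate_bootstraps(res, normalize_genes(sim$x))
#>  n_bootstraps mean_adj_r2_test consistency homogeneity mean_module_count mean_regulators_per_module
#>             2        0.8299224   0.8560606   0.8525037               4.5                   2.888889

score_recovery(res[[1]]$modules, sim$truth)
#> $mean_jaccard           0.977
#> $regulator_precision    0.923
#> $regulator_recall       1
```

Reading the numbers: in the first bootstrap the iteration starts at
sparsity 1, forms 6 clusters, retains 3 as modules, and finishes after
sparsity reaches the C₁ = 4 cap. The first module's 20 genes are explained
by 3 regulators with held-out adjusted R̄² ≈ 0.99. Across the two
bootstraps the retained modules average R̄² ≈ 0.83 on test samples, are
highly stable across the random splits (S ≈ 0.86) and internally
co-expressed (H ≈ 0.85); against the planted truth, discovered gene sets
overlap at Jaccard ≈ 0.98 and recover every planted regulator.

For real data, `read_expression()` loads a TSV
(`gene_id<TAB>sample1<TAB>...`), `set_regulators()` /`read_regulators()`
flag the driver list, and the defaults (`k = 100`, `var_fraction = 0.15`)
target a variance-filtered matrix of a few thousand genes. A command-line
interface covers the same loop: see `camodi_cli()` (`run`, `simulate`,
`evaluate`, `tune`).

## Documentation

The methods vignette (`vignettes/module-discovery.Rmd`) documents the
model and its assumptions, every tunable parameter, the synthetic
generator's scope, and the numerical conventions (path breakpoints,
cross-validation refits, tie-breaks, degenerate inputs).
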