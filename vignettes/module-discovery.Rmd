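---
title: "Methods: sparse-representation module discovery and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-representation module discovery and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camodi)
```

## The model

The package assumes a linear module model. A module `M = {G, R}` couples
member genes `G` with regulators `R` and coefficients `α`; for every member
gene `i` and sample `k` the model predicts the same value,

$$\hat s_i(k) \;=\; \sum_{j \in R} \alpha_j\, s_j(k), \qquad i \in G,$$

where the `s_j` are regulator expression values. The assumptions this
encodes, and which the user should keep in mind:

* **Linearity** — member genes track a weighted sum of regulator
  expression; saturating or switch-like regulation is out of model.
* **Shared program** — all genes in a module follow *one* prediction;
  per-gene refinements are deliberately excluded, so a module is only as
  good as its least typical member.
* **Sparsity** — a handful of regulators (bounded by `c1` per gene, `c2`
  per module) suffices. This is a statement about identifiability and
  interpretability, not biology: dense programs exist but cannot be
  distinguished reliably at cohort sample sizes.
* **Signed coefficients** — activation and repression are both allowed.
  (One reading of the model's notation restricts `α` to non-negative
  values; unconstrained elastic nets are signed, and the synthetic
  generator draws random signs by default with a `nonnegative` switch for
  probing the restricted variant.)

All expression is z-normalized per gene, so every regression runs through
the origin without an intercept.

## The discovery iteration

Each iteration (a) expresses every remaining gene as `p`-sparse
combinations of the regulators via the elastic-net path, (b) runs K-means
on the current `S1`-sparse coefficient vectors, (c) re-sparsifies each
cluster's expression centroid with the sparsity chosen by cross-validation
over the cluster's genes, and (d) retains the union of the top
`p_keep`-percent of clusters (by cross-validated R²) and all clusters
passing `cv_r2 > r_thresh` with `n_min ≤ |G| ≤ n_max`. Genes of
non-retained clusters continue with `S1` incremented by `s1_step`.

Because genes are clustered by their sparse *projection onto the regulator
basis* rather than by raw expression, clustering cost scales with the
regulator-basis dimension, not with the sample count, and early iterations
only see each gene's strongest dependencies — the design reason the
procedure starts sparse and adds complexity iteratively.

Termination is not specified by the procedure's description; this
implementation stops when (i) the next sparsity would exceed `c1` (no
complexity left to add), (ii) fewer than `n_min` genes remain, or (iii)
`max_iterations` is reached. Leftover genes are reported unassigned, never
force-assigned — the protocol's goal is a set of good modules, not full
coverage. Genes of retained modules are final and are not reconsidered.

## Parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `c1` | 10 | max regulators per gene representation; caps per-gene model complexity and bounds the sparsity ladder |
| `c2` | 10 | max regulators per module centroid; the reported regulator count never exceeds it |
| `s1_init`, `s1_step` | 1, 2 | sparsity ladder 1, 3, 5, ... capped at `c1`; simplest dependencies first |
| `k` | 100 | K-means clusters at full pool; sized for a variance-filtered matrix of ~2000–3000 genes, i.e. ~20–30 genes per cluster |
| `k_scaling` | `"scaled"` | `K_t = max(2, round(k · n_remaining/n_initial))`: the gene pool shrinks each iteration and scaling preserves the intended average cluster size (a `"fixed"` mode is provided; the choice is not settled by the source procedure) |
| `p_keep` | 10 | percent of clusters always retained per iteration; guarantees progress even when nothing clears the threshold |
| `r_thresh` | 0.6 | cross-validated R² bar for the alternative retention rule |
| `n_min`, `n_max` | 5, 1000 | size bounds for threshold retention; mirror the evaluation filter's 5–1000 gene window |
| `l2_gene`, `l2_centroid` | 0.01 | the fixed ridge penalties of the two elastic-net stages (unitless, on z-scored data); small values stabilize correlated-regulator selection without materially shrinking the path. The reference protocol tuned these per dataset but does not publish values; 0.01 is an implementation default, not a reproduced value |
| `n_folds` | 10 | gene-folds in centroid cross-validation; reduced to leave-one-out with a warning for small clusters |
| `var_fraction` | 0.15 | variance-filter fraction, computed on training samples only |
| `normalize_scope` | `"all"` | z-normalization before splitting — the reference protocol's order, reproduced deliberately even though it leaks test-sample information into the scaling; `"train"` estimates the normalization on training samples only |
| `base_seed` | 1 | all randomness (splits, K-means seeding, fold shuffles) derives deterministically from it |

Greedy coordinate-ascent tuning (`tune_parameters()`) optimizes the mean
test-side adjusted R̄² of retained modules, adopting the single-parameter
move with the largest gain until no move improves by more than 0.005.
Consistency is intentionally not part of the tuning objective.

## Numerical choices

**p-sparse extraction.** The elastic net with fixed L₂ penalty is solved as
a lasso on the ridge-augmented design `[X; √λ₂·I]`, giving the "naive"
elastic-net coefficients along the L₁ path. The `p`-sparse vector is taken
at the *smallest* path λ with exactly `p` active coefficients — the end of
the `p`-active segment, where the coefficients are meaningful rather than
freshly activated (the LARS breakpoint convention). The discretized glmnet
path occasionally jumps a sparsity level; a λ-bisection recovers it, and if
the path saturates before `p` (fewer informative regulators than requested)
the densest representation reached is carried forward. A gene that is
itself a regulator is excluded from its own basis, with a structural zero
kept at its own position so all representations share one basis dimension.

**Coefficient reporting vs. selection.** Reported coefficients are the
penalized path coefficients (a `refit` flag switches to least-squares
refits on the active set). During cross-validated sparsity selection,
however, candidates are *always* evaluated with refit active sets: the
end-of-segment shrinkage is larger for sparser models, and with shared-mean
clusters the penalized held-out R² curve creeps upward with `p` by ~1e-4,
collapsing the selection to `p = c2` every time. Refitting decouples
support selection from shrinkage; on planted three-regulator clusters the
selected sparsity then concentrates on 3, as it should.

**Module R².** The score is
`1 − Σ_k Σ_{i∈G}(ŝ(k) − s_i(k))² / Σ_k Σ_{i∈G}(s_i(k) − mean_k s_i)²` —
residual energy of the shared prediction over the module genes' total
energy (per-gene means, which are ≈ 0 after z-normalization). A
transcription of the source equation places the inner mean across the
module's *genes* per sample instead; that variant's denominator is the
module's internal noise energy, under which a perfect shared fit scores
≈ `−1/(|G|−1)` and the published magnitudes (R̄² ≈ 0.6–0.9 for retained
modules) are unattainable, so this package uses the total-energy reading
throughout, in code and in its independent test oracles. R² is not floored
at zero: negative values flag fits worse than the mean profile and must
stay visible to the retention filter. The adjusted value
`R̄² = R² − (1−R²)|R|/(m−|R|−1)` errors (rather than returning nonsense)
when `m ≤ |R|+1`.

**K-means.** Lloyd iterations with k-means++ seeding, fully determined by
the supplied seed; assignment ties go to the lowest-index centroid, so
duplicated points always share a label. A cluster that empties is re-seeded
at the point farthest from its assigned centroid, keeping `K` stable.
Convergence: unchanged labels or centroid movement below 1e-6, with a
300-iteration cap. If fewer distinct vectors than `K` exist, fewer clusters
are returned with a warning.

**Cross-validation folds** are over *genes*, shuffled by the provided seed
into near-equal folds; the held-out score uses the module R² with `G` = the
held-out genes (well defined down to a single held-out gene under the
per-gene-mean denominator). Ties in the mean held-out curve break toward
the smaller sparsity. Candidate supports are refit per fold (supports may
differ across folds); selection is by sparsity level.

**Retention** reads the two filtering rules as additive (a union), so at
least `⌈p_keep% · candidates⌉` clusters are always retained. Clusters with
fewer than 2 genes cannot be cross-validated and are excluded from
candidacy; their genes carry forward. The centroid's regulator basis
excludes regulators that are member genes of the cluster itself (the
centroid-level analogue of the self-fit exclusion).

**Ties in the variance filter** break by input order; split `i` of the
bootstrap protocol is seeded `base_seed + i`; missing values are rejected,
never imputed.

## The synthetic generator

`generate_planted()` draws regulators i.i.d. standard normal across
samples; each planted module samples a regulator subset (may overlap
between modules — gene sets never do), shared coefficients with magnitudes
uniform on `coefficient_range` and random signs, and member genes equal to
the shared signal plus independent `N(0, noise_sd²)` noise; background
genes are pure noise. All rows are z-normalized.

The default design — 10 modules of 20 genes on 2–4 regulators each, 100
background genes, noise sd 0.2, 200 samples — matches the conditions under
which the discovery procedure is exercised in the acceptance suite. Two
values are not fixed by that statement and were chosen once: a pool of 50
regulators (large enough that module regulator subsets are mostly distinct
and selection is non-trivial, small relative to the real ~3600-TF pool to
match the ~300-gene scale) and coefficient magnitudes in [0.5, 1.5] (unit
scale, keeping per-module signal-to-noise around 15–50× at noise 0.2). For
this ~300-gene world, tests use `k = 15` — the same ~20-genes-per-cluster
target the full-scale default `k = 100` encodes.

What the generator deliberately does *not* emulate: heavy-tailed and
heteroscedastic expression noise, correlated regulators, batch structure,
copy-number or methylation effects, and modules with per-gene (rather than
shared) coefficient profiles. A green recovery test therefore establishes
that the machinery works when the model's assumptions hold — not that
modules found in tumor data are biologically real, and not how the method
degrades under model misspecification beyond the noise-level sweeps in the
test suite.

## Known limitations

* The shared-prediction model ignores per-gene scaling; genes tracking a
  program with different amplitudes dilute their module's R².
* Normalizing before the train/test split (the reproduced protocol order)
  leaks test information into the per-gene scaling; use
  `normalize_scope = "train"` for a leakage-free variant.
* The coverage denominator of the reporting filter is the union of genes in
  size-filtered modules; an explicit `universe` argument switches to all
  analyzed genes (reported results are insensitive to this choice at
  moderate coverage levels).
* Discovery is single-process; per-gene sparsification is embarrassingly
  parallel by contract (results are order-independent) but no parallel
  backend is wired in.
* With strongly correlated regulators the lasso path can, at discrete
  resolution, activate two regulators between grid points; the bisection
  recovers the level in practice but an exact tie (simultaneous entry)
  falls back to the sparser representation.
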