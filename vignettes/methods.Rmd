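---
title: "Methods: translation-based spatial imputation, spatial regularization and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translation-based spatial imputation, spatial regularization and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`spotimpute` treats imputation of unprobed genes in spatial
transcriptomics (ST) as *modality translation*: a gene's expression
profile over reference cells, `x`, is mapped to its profile over ST
spots by a linear function `y = f(x)` with no bias term. The genes
shared between the reference and the ST panel supervise the fit; the
fitted map then translates any other reference gene — or any other
per-cell feature matrix, such as spliced/unspliced counts for RNA
velocity — into spot space.

Linearity without intercept assumes both matrices live on the same
expression scale. The package therefore normalizes both datasets
identically (`normalizeExpression()`, default `total_count_log1p`:
scale every sample to the median sample sum, then `log1p`); the
strategy is a configuration knob (`none`) so pre-normalized inputs pass
through untouched, and the synthetic benchmarks below train on linear
scale, where the ground-truth map is exactly linear. Whether cosine
losses are computed on log or linear scale is genuinely open; we expose
it rather than fix it, and document that the choice must be the same on
both sides.

Two parameterizations enforce nonnegativity of the mapping:

* **full mode** — `W = W̃²` elementwise, a spots × cells (or spots ×
  clusters) matrix. Used for *cluster mode*, where the reference is
  first summed into cluster pseudobulks (`aggregateByCluster()`,
  clusters sorted lexicographically for determinism).
* **low-rank mode** (default) — `W = softmax_rows(Ũ) · (Ṽ²)ᵀ` with
  latent dimension `K`. Row-softmax makes each spot a convex
  combination of `K` latent archetypes; squaring makes the cell
  loadings nonnegative. An optional clamp `vClip` bounds the squared V
  entries (a guard against overfitting observed on some tissues; the
  clamp is applied after squaring and its gradient is zero beyond the
  bound).

Cluster mode is a special case of the low-rank cell mode: fixing the
constrained cell loadings to the cell-by-cluster indicator matrix makes
the two parameterizations produce identical predictions given the same
effective spot loadings. The test suite asserts this nesting to 1e-5.

The full-mode square parameterization mirrors the V constraint; it was
chosen over e.g. softplus or projected gradients for consistency and
smooth gradients everywhere.

## Losses and training

The translation loss is the dual cosine dissimilarity

    l_trans = mean_i (1 - cos(ŷ_i., y_i.)) + mean_j (1 - cos(ŷ_.j, y_.j)),

penalizing both spot-wise and gene-wise distributional mismatch; it is
invariant to per-matrix positive rescaling, which suits expression data
where absolute scale is arbitrary. Cosine with a zero vector is defined
as 0 — the maximal penalty for that term — rather than NaN, so all-zero
genes or spots keep the loss finite; such terms receive a zero
(sub)gradient.

The spatial regularizer compares global Moran's I between predicted and
observed expression per gene, `l_spa = mean_j (Î_j - I_j)²`, and the
total loss is `l_total = l_trans + λ·l_spa` with λ = 1 by default when
regularization is on. Moran's I is computed as
`I = (Ns/S0)·(zᵀWz)/(zᵀz)` over the spot graph — a composition of
matrix products, so the gradient flows through it to the predicted
expression. Genes with zero variance across spots (imputed genes can be
constant) take `I := 0` and are flagged; they contribute `(0 - I_obs)²`
to the loss with zero gradient.

Because global Moran's I couples all spots, training is full-batch.
The optimizer is AdamW (decoupled weight decay) with the defaults
epochs = 2000, learning rate = 0.01, weight decay = 0.01, and K = 256
for low-rank modes (K = 32 suffices for the desk-scale synthetic data
used in the tests, whose ground-truth mapping has rank at most the
number of clusters). All gradients are derived analytically and checked
against central finite differences (relative error < 1e-4 in the test
suite; observed around 1e-10). Parameters initialize as N(0, 0.1²)
draws from the configured seed; there is no early stopping (a fixed
epoch budget keeps runs comparable and deterministic). Two runs with
the same seed on the same machine produce bitwise-identical loss traces
and predictions. Non-finite losses abort with the epoch and term values.

## Spatial graph

`buildSpatialGraph()` connects each spot to its `k = 6` nearest
Euclidean neighbors, converts distances to weights (default
`w = 1/(1+d)`; Gaussian and binary schemes available), symmetrizes by
elementwise maximum and row-normalizes. Distance ties resolve to the
lower spot index; duplicate coordinates are legal (zero distance gets
the scheme's maximal weight). The exact scheme and `k` used per tissue
in published analyses of this kind are rarely recoverable, so the
defaults here are stated explicitly and recorded in the run config
rather than presented as canonical.

## Uncertainty estimation

The uncertainty target is the *bootstrap variance of a gene's CSS*:
the reference is resampled with replacement within each cluster
(`localBootstrap()`; every cluster keeps its exact size, and each cell
position is refilled from its own cluster so the fitted per-cell map
stays aligned), the already-fitted map translates each of `Nsim = 20`
replicates (the model is never refitted), and the per-gene CSS against
the observed ST matrix is collected; its unbiased (n−1) variance is the
target. `Nsim` is configurable; 20 keeps the variance estimate stable
without dominating runtime. Bootstrap seeds are drawn from a dedicated
stream so bootstrap randomness never perturbs training randomness.

The regression `uncertainty = β0 + β1·sparsity + β2·predMean +
β3·predVar` is plain unregularized OLS on unstandardized features,
fitted on all training-fold genes (the alternative — a sub-split of the
training genes — is noted but not used; with hundreds of genes and four
coefficients overfitting is not a concern). Predicted scores are ranked
into quantiles (average ranks on ties).

Gene selection builds the curve of median CSS over genes at or below
each uncertainty quantile (grid 10%…100%) and places the threshold at
the knee — the grid point with maximal perpendicular distance to the
chord joining the curve endpoints; a flat curve falls back to the most
stringent quantile. "Knee point" admits many definitions; the
max-distance-to-chord rule is parameter-free and deterministic. A
cross-validated alternative (`method = "cv"`) picks the quantile
maximizing mean held-out median CSS across folds.

## Evaluation machinery

* `kfoldSplit()` shuffles genes with a seed and chunks contiguously;
  merged test folds cover every gene exactly once (fold sizes differ by
  at most one).
* `cssSummary()` reports per-gene (column) or per-spot (row) cosine
  scores with the median as the headline aggregate.
* `moransITest()` tests for positive spatial autocorrelation, one-sided
  (spatially variable genes are by definition positively
  autocorrelated). The default is a seeded permutation test with
  `p = (1 + #{I_perm ≥ I_obs}) / (1 + nPerm)` — exact under
  exchangeability and reliable for sparse genes; the classical
  normality-assumption z-test is available for speed. BH adjustment
  controls FDR across genes; the conventional SHVG cutoff is q < 0.01.
* `shvgPrc()` takes significance calls on *observed* expression as
  truth and ranks genes by the Moran z statistic on *imputed*
  expression (the ranking variable is a design choice; the z statistic
  is monotone in evidence strength and comparable across genes), then
  sweeps all thresholds; AUPRC uses step integration.
* `spatialAgglomerativeClustering()` is bottom-up Ward agglomeration in
  which merges are restricted to graph-connected cluster pairs, so
  clusters stay spatially contiguous; if the requested cluster count is
  below the number of graph components, the remaining merges ignore
  connectivity. Ties resolve to the smallest index pair. Expression is
  z-scored per gene beforehand (configurable). Ward linkage was chosen
  as the standard variance-minimizing criterion; the connectivity
  constraint is implemented in-package because no installed R routine
  offers constrained agglomeration.
* `clusteringConcordance()` reports ARS, AMIS (expected mutual
  information under the hypergeometric null), homogeneity and NMI
  (arithmetic normalization) plus their mean. Concordance can be
  computed either between clusterings of imputed and observed
  expression or against an external annotation; both views are
  supported and the report does not privilege one.

## Synthetic data design

`simulateSpatialData()` builds the study conditions for every test:

* **Reference** — `nClusters` log-normal gene programs; cells get their
  cluster's program times log-normal jitter; Bernoulli dropout zeroes
  entries at `dropoutRate` (default 0.3, a typical imaging-reference
  sparsity). A Poisson-sampled copy provides a true count matrix for
  the sparsity feature.
* **Mapping** — spots live on a regular grid; each cluster gets a
  Gaussian bump of width `smoothSigma` (grid units); each spot mixes
  its ≤ 3 nearest cluster bumps, and within-cluster cell weights are
  fixed per cluster, so `W_true` is nonnegative with rank ≤
  `nClusters`. The default grid makes Moran's I oracles and visual
  checks trivial.
* **ST** — `st = W_true · ref + N(0, noiseSd²)` clipped at zero
  (default `noiseSd = 0`). Because ST is an exact linear image of the
  returned reference, the data are reachable by the full-mode model
  class and noiseless recovery is well-posed. Genes in the spatial mask
  (`fracSpatialGenes = 0.5`) receive strongly cluster-differential
  programs, so their spot profiles follow the spatial cluster blocks;
  flat genes have cluster-constant means. Note that with zero noise
  *every* gene inherits some smoothness from `W_true` (Moran's I is
  scale-free), so the spatial/flat Moran contrast is assessed under
  measurement noise, where the flat genes' low-amplitude component is
  drowned out — the realistic regime. Per-gene target Moran's I of the
  noiseless ST is stored in the returned truth object.

`addWhiteNoise()` adds seeded Gaussian noise (optionally to a gene
subset) and clips at zero; large noise drives per-gene Moran's I toward
zero, which stress-tests the regularizer and, applied heavily to half
of the reference genes, creates the poorly-imputable gene population
used to validate the uncertainty score.

What the generator does **not** emulate: platform-specific noise
(segmentation error, bleed-through), batch effects between reference
and ST, non-linear reference→spot relationships, and realistic gene–gene
correlation structure beyond cluster programs. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
assumptions, not performance on any particular tissue or platform.

## Problem sizes and tolerances

The test and acceptance runs use desk-scale instances chosen to make
every property decidable in minutes on one CPU: 200 cells × 100 spots
(10×10 grid) × 100 genes with 5 clusters for end-to-end checks (K = 32,
rank-8 truth), 36-spot instances for unit tests, 500 null genes with
199 permutations for test calibration (the permutation p-value grid
makes the nominal 0.05 level exact under exchangeability), and noisy
runs at `noiseSd` equal to 10% of the clean ST standard deviation.
Key tolerances: Moran's I against the double-loop oracle at 1e-10;
analytic vs finite-difference gradients at 1e-4 relative; cluster/low-rank
nesting at 1e-5; recovery thresholds of 0.99 (clean) and 0.90 (noisy)
median held-out CSS.

## Known limitations

* Training is full-batch; very large spot counts would need the
  mini-batch/local-autocorrelation variants deliberately left out of
  scope.
* The checkpoint format is an RDS archive — portable across R versions
  but not across languages.
* HDF5-based input is not supported in this build; use MTX + sidecars
  or delimited text.
* The uncertainty regression is linear by construction; it captures the
  dominant monotone relationship between its three features and
  bootstrap variance but cannot model interactions.
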