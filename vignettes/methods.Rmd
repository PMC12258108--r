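---
title: "Methods: network-smoothed selection, module refinement and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-smoothed selection, module refinement and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`prognet` targets two-class expression studies with survival follow-up:
a genes × samples log-scale matrix, a per-sample phenotype (class −1 =
poor prognosis, +1 = favorable; survival time in days; event indicator;
optional batch), and an undirected gene network. The pipeline is

1. batch residualization and per-gene standardization,
2. network-smoothed t-statistic selection gated by log fold change,
3. repeated stratified cross-validation with a linear maximum-margin
   classifier, scored by AUC,
4. co-expression module detection on the selected candidates,
5. minimum-spanning-tree hub extraction from the strongest module edges,
6. per-gene median-split Kaplan–Meier comparison.

## Differential statistics

`differential_stats()` uses the pooled-variance two-sample t-statistic;
its sign convention is positive when expression is higher in the
poor-prognosis class, and `logfc` is the difference of class means on
the log scale. A moderated (shrunken-variance) t is deliberately *not*
the default: the plain statistic has a closed form that the test suite
can verify directly, and at the sample sizes this pipeline targets
(hundreds of samples) moderation changes little.

## The random-walk kernel and its normalization

`build_kernel()` returns the p-step random-walk kernel
$K = (aI - \tilde L)^p$ on the symmetric normalized Laplacian
$\tilde L = I - D^{-1/2} A D^{-1/2}$ (diagonal of $\tilde L$ is 1
everywhere; an isolated node has a zero normalized-adjacency row, so its
kernel diagonal is $(a-1)^p$). Since the spectrum of $\tilde L$ lies in
$[0, 2]$, $a \ge 2$ guarantees positive semi-definiteness; the
constructor rejects $a < 2$. Defaults $a = 2$, $p = 3$: three diffusion
steps reach the 3-hop neighborhood, which on scale-free interaction
graphs already covers most of a module's local cluster, while staying
cheap (dense matrix powers by repeated squaring).

`smooth_scores()` computes $s = K'|t|$ with, by default, the
degree-normalized kernel $K' = S^{-1/2} K S^{-1/2}$,
$S = \mathrm{diag}(\text{rowSums } K)$. This is the one place the
implementation deviates from the plain $K|t|$ formulation, and it is a
considered choice: row sums of $(aI - \tilde L)^p$ grow with node
degree, so unnormalized smoothing ranks hub genes highly *regardless of
their statistics*. In the package's own synthetic benchmark
(1000 genes, 200 samples, 20 planted genes) the unnormalized smoother
recalls *fewer* planted genes than raw $|t|$ at moderate-to-strong
effects, defeating the purpose of smoothing; the degree-normalized form
recovers more at every effect size tested. Because the normalization is
a congruence transform, $K'$ remains symmetric, PSD and entry-wise
non-negative; on regular graphs and isolated nodes it changes nothing,
and all limiting behaviors are preserved ($p = 0$ gives exactly the raw
$|t|$ ranking). `normalize = FALSE` restores the plain form.

Smoothed scores are rescaled to $[0,1]$ by the maximum before ranking —
purely cosmetic, order-preserving. Ties are broken alphabetically by
gene symbol so ranks are deterministic.

## Selection gates

`select_signature()` keeps genes ranked within the top `top_frac`
(ceiling rule) **and** with $|logfc| \ge$ `min_abs_logfc`. Defaults
`top_frac = 0.1`, `min_abs_logfc = 0.5`: the top decile is a common
operating point for signature-scale selection, and half a log-unit is
the conventional "biologically visible" fold-change floor. The gate is a
conjunction: a rank-1 gene with flat fold change is excluded. Both knobs
are mandatory-visible in the CLI.

## Cross-validation

`run_cv()` runs repeated stratified k-fold CV (default 10 × 5). All
data-dependent steps — per-gene standardization, differential
statistics, smoothing, gating, classifier fitting — happen inside the
training fold; the held-out fold is transformed with training-fold
parameters only. The classifier is an L2-regularized squared-hinge
linear SVM (cost 1 by default) solved by BFGS: the objective is convex,
so the fit is deterministic, which underwrites the byte-reproducibility
contract. A fold whose signature comes out empty scores AUC 0.5 (chance)
with a warning rather than failing the run. AUC is the rank-based
Mann–Whitney form with half-credit for ties. `consensus()` aggregates
fold signatures by selection frequency (default threshold 0.5,
boundary inclusive) — the aggregation rule is this package's explicit
choice, since frequency is the simplest statistic that exposes
signature stability.

One integer seed drives fold assignment; everything downstream is
deterministic given the fold split, so a `cv_result` is a pure function
of (data, parameters, seed).

## Co-expression modules

The scan (`scan_soft_threshold()`) uses unsigned adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ and the signed scale-free fit
index: $-\mathrm{sign}(\text{slope}) \cdot R^2$ of the regression of
$\log_{10} p(k)$ on $\log_{10} k$ over 10 equal-width connectivity bins
(empty bins dropped). The sign convention makes the index *positive*
when the degree distribution decays — the only direction in which
"scale-free" is meaningful — so the smallest β reaching `r2_cut`
(default 0.85) is chosen; if none reaches it, the argmax with a
warning. Candidate powers default to 1..20.

`tom()` implements the unsigned topological overlap
$TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$,
diagonal 1. `detect_modules()` clusters $1 - TOM$ with average linkage
and a **static** cut (default height 0.8, minimum size 10, smaller
clusters relabeled grey); static cutting is simpler and fully testable,
at the cost of missing nested module structure a dynamic cut would find.
Module labels follow the conventional color order by decreasing size
(turquoise first). Eigengenes are unit-norm first principal components,
sign-oriented to correlate positively with their module's genes;
module–trait association is Pearson r with a two-sided t-transform
p-value on n − 2 degrees of freedom.

One practical note: the static cut at 0.8 presumes TOM similarities
large enough that within-module dissimilarity falls below the cut. For
block-correlated data this means small powers (β ≈ 1–2); the scale-free
cut criterion does not apply to block worlds (their degree distribution
is bimodal, not power-law), so the package's block-model tests fix
β = 2 rather than chaining the scan into detection.

## Hubs

`filter_edges()` keeps the ceiling `top_frac` fraction of edges by
weight (0.3 is the conventional operating point), ties broken by
lexicographic node pair. `mst_hubs()` maps similarities to distances
$d = 1 - w/\max(w)$ (strongest co-expression = shortest distance) and
builds the minimum spanning forest with a deterministic Kruskal (sorted
by distance, then node pair), so tied weights cannot introduce run-to-run
variation. The hub score is MST degree — the simplest centrality that
rewards genes holding the tree together — with tree betweenness behind a
flag; since Kruskal depends only on the *order* of weights, the selected
edge set is invariant under any order-preserving weight transform.

## Survival

`km_fit()` is the product-limit estimator; at tied times events precede
censorings (the censored subject remains in the risk set at its own
time). "Wilcoxon test" for survival is interpreted as the
Gehan–Breslow–Wilcoxon weighted log-rank — the standard survival
Wilcoxon — with weight equal to the total number at risk at each event
time, statistic $(\sum w_j (O_j - E_j))^2 / \sum w_j^2 V_j$ referred to
$\chi^2_1$; plain log-rank is the `method = "logrank"` flag. Median
splits assign ties to the low group. `survival_screen()` reports raw
p-values plus a clearly-labeled Benjamini–Hochberg column; whether to
adjust across genes is left to the analyst.

# The synthetic world

`sim_config()` fixes a fully seeded generative model:

| parameter | default | meaning |
|---|---|---|
| `n_genes` × `n_samples` | 1000 × 200 | matrix size; classes balanced |
| graph | preferential attachment, m = 2 | connected scale-free network, exactly 2n − 3 edges |
| `signature_size` | 20 | planted genes, a BFS-connected subgraph |
| `effect_size` | 0.5 | standardized mean shift in the poor class |
| `module_blocks`, `rho` | 3, 0.6 | block factor model; signature sits in block 1 |
| `batch_shift` | 0 (off) | additive shift on a random half of samples |
| `baseline_hazard` | 3e-4 / day | exponential survival; ~6-year median |
| `hazard_coef` | 1 | log-hazard per unit mean signature expression |
| `censor_frac` | 0.3 | censoring rate, calibrated analytically |

Expression is $x_{gi} = \sqrt\rho f_{b(g),i} + \sqrt{1-\rho}\,
\varepsilon_{gi}$ with standard normal factors and noise, so every gene
has unit variance and `effect_size` is directly a Cohen-type d. Class
labels are drawn first (balanced) and expression generated
conditionally. Survival hazard is $\lambda_0 e^{\beta_h z_i}$ with
$z_i$ the mean signature expression; the censoring rate is solved
analytically so the expected censored fraction hits the target. The
batch shift is added *after* survival generation, making batch a pure
nuisance variable.

Default effect size 0.5 was chosen a priori as a moderate effect: at
n = 200 it gives per-gene $|t| \approx 3.5$ against a 1000-gene noise
floor of about 3.2, i.e. selection is hard but not hopeless. The
network advantage of smoothing is largest for weaker effects (per-gene
statistics individually below the noise floor, jointly recoverable
through their connectivity); at strong effects (≥ 1.5) raw and smoothed
selection both saturate and cannot be distinguished.

**What a green test establishes — and what it does not.** The generator
covers the *statistical* structure the method assumes: connected
differential subnetwork, correlated co-expression blocks, additive
batch, hazard coupled to signature expression, independent exponential
censoring. It does not emulate microarray/RNA-seq noise models
(mean–variance coupling, counts), probe-level artifacts, informative
censoring, unbalanced or drifting classes, or a PPI graph with false
edges at realistic rates. Green tests therefore certify internal
correctness and behavior in the stated world, not clinical performance.

# Numerical and convention choices

- Standard deviations use the n − 1 denominator throughout.
- Duplicate gene rows collapse to the highest-mean row; duplicate edges
  merge by maximum weight; self-loops are dropped with a count.
- Genes measured but absent from the network are kept as isolated nodes,
  so smoothing degenerates to the raw statistic for them rather than
  silently discarding measurable genes.
- Samples censored before the dichotomization cutoff are excluded (their
  class is unknowable); the exclusion count is logged.
- Batch removal protects the class covariate in the design and rejects
  designs where batch is aliased with class (rank check), rather than
  silently absorbing the signal of interest.
- Writers format numerics as `%.17g`, so read → write → read round-trips
  are bit-exact and CLI outputs are byte-stable across runs.
- All tie-breaks (ranks, edge filtering, Kruskal, hub ordering) are
  lexicographic on gene symbols — determinism over elegance.
- Time is canonically days; phenotype headers may declare
  `time_days|months|years` and are converted on load (30.4375-day
  months, 365.25-day years).

# Known limitations

- Static tree cut (no dynamic hybrid cutting) and unsigned networks
  only; no block-wise processing for very large gene sets.
- The linear classifier is the only model offered; no hyperparameter
  search beyond the exposed cost constant.
- The Gehan–Wilcoxon p-value is asymptotic ($\chi^2_1$); for very small
  groups a permutation p is the better tool (the test suite checks the
  asymptotic p against a permutation null at n = 30).
- `remove_batch` fits additive batch terms only — no empirical-Bayes
  shrinkage and no batch × gene interaction.
- The hub criterion (MST degree) is one defensible centrality among
  several; betweenness is offered, eigenvector-style scores are not.
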