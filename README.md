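# prognet

Network-smoothed feature selection and survival stratification for
prognostic biomarker discovery in two-class expression studies.

## The problem

Expression cohorts for heterogeneous cancers (the motivating setting is
pediatric neuroblastoma, with patients dichotomized at 5-year overall
survival into poor, `-1`, and favorable, `+1`, prognosis groups) rarely
yield stable single-gene prognostic markers: per-gene statistics are
noisy at realistic sample sizes, and top-k lists churn across folds.
`prognet` implements a network-based selector that borrows strength
across a protein-protein interaction (PPI) graph, then refines the
selected signature into hub genes and tests their survival impact.

## The method

**Selection.** For each gene, a pooled-variance two-sample t-statistic
`t_g` (positive = higher in the poor-prognosis class) and the log fold
change are computed. Absolute statistics are smoothed over the PPI graph
with a p-step random-walk kernel

```
K = (a·I − L̃)^p ,   L̃ = I − D^{−1/2} A D^{−1/2} ,   a ≥ 2, p ≥ 0
```

(`a = 2`, `p = 3` by default; `a ≥ 2` keeps `K` positive semi-definite
because the spectrum of `L̃` lies in `[0, 2]`). Smoothed scores are
`s = K′|t|` with `K′` the degree-normalized kernel
`S^{−1/2} K S^{−1/2}`, `S = diag(rowSums K)` — the normalization removes
the raw kernel's hub bias while preserving symmetry, PSD-ness and all
limiting behavior (`p = 0` reduces exactly to raw `|t|` ranking). Genes
are kept when they rank in the top fraction (`top_frac`, default 0.1)
**and** clear a log-fold-change gate (`min_abs_logfc`, default 0.5).

**Validation.** Repeated stratified k-fold cross-validation (default
10 × 5): selection and an L2-regularized squared-hinge linear SVM are
fit inside each training fold only; held-out decision values are scored
by rank-based AUC. A consensus signature collects genes selected in at
least half the folds.

**Refinement.** On a candidate set, WGCNA-style co-expression analysis:
soft-threshold scan against approximate scale-free topology, unsigned
topological overlap (TOM), average-linkage module detection, module
eigengenes and eigengene-trait correlations. The strongest 30% of edges
of the interesting module feed a minimum-spanning-tree hub extraction
(hub = high MST degree), optionally intersected with an external
regulator list.

**Survival.** Per gene, samples are split at median expression and the
high/low Kaplan-Meier curves compared with the Gehan-Breslow-Wilcoxon
weighted log-rank test (weight = number at risk; plain log-rank
available), with Benjamini-Hochberg adjustment across genes.

A seeded generator (`sim_config()` / `simulate_dataset()`) produces the
stated synthetic world — scale-free network, connected planted
signature, block-correlated expression, optional batch shift, hazard
coupled to signature expression — and every test and acceptance quantity
runs against it.

## Worked example

```r
library(prognet)

cfg <- sim_config(n_genes = 500, n_samples = 150, signature_size = 15,
                  effect_size = 1, seed = 42)
d <- simulate_dataset(cfg)

stats <- differential_stats(standardize(d$expr), d$pheno)
kern  <- build_kernel(d$net, a = 2, p = 3)
sig   <- select_signature(smooth_scores(stats, kern),
                          top_frac = 0.1, min_abs_logfc = 0.5)
sig
#> gene_list 'top 10% & |logFC| >= 0.5': 15 gene(s)
#>   g0011, g0091, g0043, g0132, g0260, g0050, g0182, g0146, g0285, g0221 ...
sum(d$truth$signature %in% sig)
#> [1] 15                      # all 15 planted genes recovered

cv <- run_cv(d$expr, d$pheno, d$net, repeats = 10, folds = 5, seed = 1)
cv
#> cv_result: 10 repeat(s) x 5 fold(s), median AUC = 0.729
cons <- consensus(cv, min_freq = 0.5)

survival_screen(d$expr, d$pheno, genes = as.character(cons)[1:5])
#>    gene n_low n_high statistic        p     p_bh
#> 1 g0002    75     75      21.7 3.19e-06 7.97e-06
#> 2 g0007    75     75      10.3 1.31e-03 1.31e-03
#> 3 g0009    75     75      15.9 6.85e-05 8.56e-05
#> 4 g0011    75     75      16.2 5.79e-05 8.56e-05
#> 5 g0017    75     75      22.4 2.26e-06 7.97e-06
```

The selector recovers the full planted signature; the held-out median
AUC (0.729 at this moderate effect size, rising above 0.85 at strong
effects) quantifies how well the signature generalizes; the screen shows
each consensus gene's median-split survival separation with raw and
BH-adjusted Gehan-Wilcoxon p-values.

Every stage is also exposed as a CLI (`simulate`, `preprocess`,
`select`, `crossval`, `modules`, `hubs`, `survive`), e.g.

```sh
Rscript -e 'prognet::prognet_cli()' simulate --n-genes 500 --seed 1 --out-dir data/
Rscript -e 'prognet::prognet_cli()' select --expr data/X.tsv --pheno data/P.tsv \
    --net data/ppi.tsv --top-frac 0.1 --min-logfc 0.5 --out signature.txt
```

Outputs are byte-reproducible for a fixed seed/config.

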