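---
title: "Methods: aging-related transcripts, network modules, and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging-related transcripts, network modules, and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agesurv` implements a transcriptomic pipeline for cohorts of cancer
patients with paired normal/tumor expression and clinical follow-up: find
transcripts whose expression in *normal* tissue changes with chronological
age, summarize them into per-patient aging indices, and ask whether those
indices — rather than tumor-derived markers alone — carry prognostic
information. This vignette is the package's account of the underlying
models, the knobs that matter, and the choices made where the design was
genuinely open.

## The dual regression models

For each transcript $j$ the package fits two ordinary-least-squares models
on the per-sample modeling scale $y_{ij}$ (by default
$\log_2(x_{ij}+1)$):

$$\mathrm{M1}: \; y_{ij} = \beta_j + \gamma_j\,\mathrm{Age}_i + \epsilon_{ij}$$

$$\mathrm{M2}: \; y_{ij} = \beta_j + \gamma_j\,\mathrm{Age}_i +
  \textstyle\sum_{k \in S} \alpha_{jk}\,\mathrm{PC}_{ik} + \epsilon_{ij}$$

where $\mathrm{PC}_{ik}$ are sample-space principal components of the
gene-standardized expression matrix, computed once per matrix, and $S$ is
the subset of the top ten components whose Pearson correlation test
against age has $p > 0.05$. Excluding age-correlated components keeps the
adjustment from absorbing the very signal being estimated; the components
that remain soak up latent structure (batch-like factors, cellular
composition) that would otherwise inflate residual variance. A transcript
is called aging-related when the age coefficient is significant
($p < 0.05$, two-sided t-test) in **both** models with agreeing signs; the
direction (increasing/decreasing with age) is the adjusted model's sign.
M1/M2 sign disagreements are demoted to no call.

Two deliberate properties of this rule deserve emphasis:

* **No multiple-testing correction is applied in selection.** The
  procedure is a raw dual $p<0.05$ screen; the guard against fragile calls
  is bootstrap stability, not FDR control. Consequences are discussed
  under *Limitations*.
* **The modeling scale is $\log_2(x+1)$** by default
  (`log2_transform = TRUE`). FPKM-like units are heavy-tailed, and a
  linear age trend is far more plausible on the log scale;
  `log2_transform = FALSE` preserves the literal raw-scale reading.

### Bootstrap stability

`bootstrap_stability()` repeats the whole selection (including PC
re-estimation) on `B = 100` resamples of patients drawn with replacement.
A called transcript's *stability* is the fraction of resamples in which it
is re-selected with the same direction; calls below `retain_frac = 0.5`
are demoted. Both values are configuration keys.

### Aging indices

The increasing (decreasing) index is the per-sample mean over the
age-upregulated (age-downregulated) transcripts. Three modes exist: `raw`
(mean of stored values), `log2` (mean of $\log_2(x+1)$), and the default
`zscore` (mean of per-gene z-scores of $\log_2(x+1)$). The z-score mode is
the default so that no single highly expressed gene dominates the average;
`raw` and `log2` are retained for fidelity checks. The two indices are
strongly (negatively) correlated by construction and are never used in one
model together.

## Survival linkage

`fit_cox_univariate()` fits a univariate Cox proportional-hazards model by
partial likelihood with **Efron** tie handling (Breslow behind a flag);
index covariates are standardized by default, so hazard ratios are per SD
— the indices have no natural unit, and an unstandardized HR would be
arbitrary. Wald p-values are reported. `median_split()` dichotomizes at
the sample median with ties assigned to the low group (deterministic), and
`km_estimate()`/`logrank_test()` provide the product-limit curves and the
two-group log-rank test. Auxiliary tests from the downstream biology
(metastasis contingency, two-group comparisons) are exposed as
`fisher_exact()` and `two_group_ttest()` (Welch by default).

## Paired differential expression

`paired_deg()` computes per-patient paired differences
$d_i = \log_2(\mathrm{tumor}_i+1) - \log_2(\mathrm{normal}_i+1)$ per gene,
takes the mean as the log2 fold change, tests it with a one-sample t-test,
and applies Benjamini–Hochberg across genes. Calls require
$|\mathrm{log2FC}| > 2$ *and* adjusted $p < 0.01$, symmetrically for up
and down. This is deliberately **not** a count-level negative-binomial
caller: no dispersion shrinkage, no size-factor normalization. The paired
design plus thresholds is the point; the output header records the
simplification.

## Network modules

Aging-related transcripts are mapped onto a protein–protein interaction
network and clustered by connectivity-weighted proximity:

1. **Diffusion kernel.** $K = e^{-\beta L}$ with $L = D - A$, computed by
   eigendecomposition per connected component. $K$ is symmetric positive
   semidefinite with unit row sums; $\beta$ (default 1.0, a configuration
   key) sets the diffusion horizon — small $\beta$ sees only immediate
   neighbors, large $\beta$ blurs the whole component.
2. **Dissimilarity.** The kernel-induced feature-space distance
   $d_{ij} = \sqrt{K_{ii} + K_{jj} - 2K_{ij}}$ (a cosine-style
   normalized alternative is available). Node pairs in different
   components carry no diffusion signal; their distance is set to the
   largest within-component distance plus one, so they always merge last.
3. **Hierarchical tree.** Agglomerative clustering with **Ward linkage**
   by default. This was a genuinely open choice that implementation
   settled: on diffusion-kernel distances, average linkage chains —
   high-degree nodes have inflated self-similarity $K_{ii}$, which pushes
   them away from their own module's core, and single outlying nodes then
   absorb the entire tree one leaf at a time. Ward's variance criterion is
   robust to this geometry and recovers planted communities reliably;
   average linkage remains available (`method = "average"`) for cleanly
   separable geometries.
4. **Dynamic tree cut.** A deterministic adaptive branch decomposition:
   the dendrogram is cut at the midpoint of the largest gap in its merge
   heights — the height band where branch structure is most clearly
   separated — and every resulting branch with at least `min_size` leaves
   becomes a module; smaller branches stay unassigned. The minimum size is
   5 by convention, raised to 25 for very large gene sets. Module labels
   are deterministic (size, then alphabetically smallest member), so
   results do not depend on node input order.

`module_survival_screen()` then builds, per module and per direction, the
expression index of the module's members with that direction and fits the
univariate Cox model — the per-module analogue of the global index
linkage.

## Survival prediction comparison

`compare_feature_sets()` compares five logistic-regression feature
configurations against vital status: the mean tumor expression of down-
and of up-regulated DEGs, the decreasing and the increasing index in
normal tissue, and the combination of the up-DEG mean with the increasing
index. Each is evaluated by `cv_logistic_auc()`: repeated (default 1000,
tests and the bundled pipeline use 100 with identical machinery) 5-fold
cross-validation, folds stratified by class, one AUC per repetition
computed from the **pooled** out-of-fold predicted probabilities. Pooling
keeps small or single-class test folds well-defined at cohort sizes where
a fifth of the deceased class is a handful of patients. The increasing and
decreasing indices are never placed in the same model: they are strongly
correlated and multicollinearity would dilute both.

Two further choices are documented caveats rather than neutral defaults:
the binary label is vital status at last follow-up, so censored patients
count as alive; and fold stratification is on by default because the
deceased class is small in the motivating cohorts.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every downstream stage. Per
gene, log2 expression is intercept ($\mathcal{N}(6, 1.5^2)$, FPKM-like) +
age slope + latent-factor loadings + Gaussian noise; the matrix is
exponentiated and zero-inflated. Ages are $\mathcal{N}(61, 14.8^2)$
truncated to $[20, 90]$ — the demographics of a mid-sized solid-tumor
cohort. Planted age slopes are parametrized by `slope_scale` $s$ such that
the population correlation between age and log2 expression is
$s/\sqrt{1+s^2}$; the default corresponds to $r = 0.35$, a moderate,
realistically detectable aging effect (`slope_scale_for_cor()` inverts the
relation). The tumor matrix shares the same log2 signal plus multiplicative
shifts of $\pm 3$ log2 units on planted DEG genes (clearing the $|{\rm
log2FC}| > 2$ filter with margin) and mild extra noise so paired
differences are non-degenerate.

Zero-inflation is **expression-dependent**: entries drop out with logistic
probability in their underlying log2 expression, calibrated so the overall
zero fraction matches `zero_inflation_rate` (default 5%). An iid
mechanism was rejected during implementation: zeroing well-expressed
entries creates enormous log-scale outliers that attenuate the planted
correlations far below their nominal value, breaking the generator's own
contract; real RNA-seq dropout concentrates in lowly expressed
measurements, which is what the logistic mechanism emulates.

Survival is exponential with hazard
$\lambda_i = \lambda_0 \exp(\theta z_i)$, where $z_i$ is the standardized
true increasing index (default $\theta = \log 2$ per SD,
$\lambda_0 = 0.1$/year), with independent Uniform$(0, c_{\max})$
administrative censoring, $c_{\max}$ solved numerically to hit the target
censor fraction (default 30%).

What the generator does **not** emulate: negative-binomial count noise and
dispersion–mean trends, batch effects, copy-number structure, and
informative censoring. Passing tests on these cohorts demonstrate that the
machinery is correct and calibrated under its own assumptions — not that
the biological findings of any particular cohort replicate.

`simulate_ppi()` generates planted-partition interaction networks
(within-module edge probability `p_in`, between `p_out`), the standard
benchmark for community recovery; `simulate_mirna()` produces an RPM-like
zero-inflated matrix for the miRNA preprocessing branch (quantile
normalization with average-rank tie handling, and the strict
"more than 70% zeros" removal rule).

## Numerical and degenerate-input conventions

* Exact (zero-residual) age relations get $p = 0$ — perfectly significant
  — while constant responses get $p = \mathrm{NA}$ and are never called.
* Singular designs abort with the collinear columns named; per-gene
  failures inside a batch are logged and skipped, never fatal.
* With 30 samples or fewer the low-expression filter switches to the
  ≤30%-zeros rule (the "nonzero in more than 30 samples" rule is
  unsatisfiable at $N \le 30$); all zero-fraction comparisons are strict
  as stated.
* Quantile normalization gives ties the mean of the reference values at
  their rank positions (average ranks, linear interpolation).
* `median_split()` sends ties at the median to the low group.
* All pipeline randomness derives from configuration seeds; two runs of
  the same configuration are byte-identical (`output_checksums()`).

## Problem sizes

The bundled default pipeline configuration analyses 150 patients × 2000
genes with 100 planted aging genes and 100 planted DEGs, a 200-miRNA
matrix, a 300-node network, bootstrap $B = 100$ and 100 CV repetitions —
sizes chosen so a full run, including the bootstrap, completes in well
under a minute on a laptop while every stage still operates in its
intended regime. The test suite uses the same machinery at these or
smaller sizes.

## Limitations

* **The selection rule does not control FDR.** With a raw dual $p < 0.05$
  screen, false calls arrive at roughly the single-test level; bootstrap
  stability removes only those whose association is fragile *within the
  sample*. A null gene whose sample correlation with age is, say, 0.17
  by chance reproduces that correlation in bootstrap resamples, so
  stability filtering cannot push the false discovery *rate* below the
  level set by the signal-to-null ratio: with ~5% planted signal the
  realized FDR sits near 0.25 even though the false positive rate stays
  near 3%. Users who need FDR control should apply
  `benjamini_hochberg()` to the reported p-values instead of the raw
  threshold.
* **A single cohort's null CV-AUC is not 0.5.** The mean over CV
  repetitions estimates that cohort's chance discrimination, which varies
  between cohorts by roughly ±0.06 at $n = 100$; repetitions share the
  data and cannot average it away. Calibration statements therefore
  aggregate over independent cohorts.
* Latent structure shared across genes makes gene-level p-values
  dependent; calibration diagnostics that assume independence (e.g.
  uniformity tests) are only well-posed on latent-free nulls.
* The paired DEG caller is a log-scale t-test, not a count model; at very
  low expression its behavior diverges from negative-binomial callers.
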