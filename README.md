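# agesurv

Aging-related transcript discovery and survival linkage in paired
normal/tumor expression cohorts.

## The problem

Cancer cohorts with paired normal/tumor RNA-seq and clinical follow-up
make it possible to ask a question that tumor-only marker studies cannot:
does the *aging state of the patient's normal tissue* — not just the
tumor's expression program — predict survival? `agesurv` implements the
full analysis for that question, exercised end-to-end on synthetic cohorts
with planted ground truth:

1. **Preprocessing** — protein-coding filter, low-expression filters
   (nonzero in >30 samples, or ≤30% zeros for small cohorts), quantile
   normalization and a strict >70%-zeros filter for miRNA.
2. **Aging-transcript selection** — per transcript, two OLS models on
   log2 expression: M1, `expr ~ age`, and M2, `expr ~ age + PCs`, where
   the PC covariates are the top-ten sample-space principal components
   *not* correlated with age (Pearson test p > 0.05). A transcript is
   aging-related iff the age coefficient has p < 0.05 in both models with
   agreeing sign; calls are then filtered by bootstrap stability (B = 100
   resamples, retain at stability ≥ 0.5).
3. **Aging indices** — per-sample mean (default: of per-gene z-scores of
   log2 expression) over the increasing and decreasing gene sets.
4. **Survival linkage** — univariate Cox models (Efron ties, HR per SD),
   Kaplan–Meier curves with median split, log-rank tests; Fisher's exact
   and Welch t-tests for clinical contingencies.
5. **Paired DEG calling** — per-patient paired log2 differences,
   one-sample t-test, Benjamini–Hochberg; called at |log2FC| > 2 and
   adjusted p < 0.01.
6. **Network modules** — aging genes mapped onto a protein-interaction
   network; diffusion kernel K = exp(−βL), kernel-induced distances,
   Ward-linkage tree, dynamic tree cut with a minimum module size (5, or
   25 for very large gene sets); per-module survival screen.
7. **Survival prediction** — five logistic-regression feature sets
   (down-DEG mean, up-DEG mean, decreasing index, increasing index,
   up-DEG + increasing combo) compared by repeated 5-fold
   cross-validation, one AUC per repetition from pooled out-of-fold
   predictions.

Everything is tidyverse-native: data frames in, tibbles out, `autoplot()`
for curves/AUC distributions/volcanoes, `tidy()`/`glance()` for fitted
objects. See the methods vignette
(`vignettes/aging-survival-pipeline.Rmd`) for models, assumptions and
limitations.

## Worked example

```r
library(agesurv)

# synthetic cohort: 150 patients x 2000 genes, 100 planted aging genes,
# survival driven by the true increasing index at log HR = log(2) per SD
report <- run_pipeline(agesurv_config(), out_dir = "agesurv_out")
report
```

```
# Pipeline run report

- samples: 150
- genes: 2000 in, 2000 after filters
- aging transcripts: 67 increasing, 50 decreasing
- paired DEGs: 49 up, 43 down
- network modules: 2

## Survival linkage

covariate	hazard_ratio	p_wald	p_logrank	n	n_event
increasing_index	1.9957	7.875e-9	2.283e-5	150	105
decreasing_index	0.59808	1.8276e-6	0.0011039	150	105
age_years	1.8529	9.0282e-9	2.0687e-6	150	105

## Survival prediction (mean CV AUC)

config	mean_auc	sd_auc	folds	reps
increasing_index_normal	0.69392	0.0058097	5	100
combo_upDEG_plus_increasing	0.68195	0.010024	5	100
decreasing_index_normal	0.64274	0.0087952	5	100
down_DEG_tumor_mean	0.6062	0.0086243	5	100
up_DEG_tumor_mean	0.48764	0.029369	5	100
```

Reading the output: 117 transcripts are called aging-related (100 were
planted); the increasing index carries a hazard ratio of ~2.0 per SD —
the planted log(2) effect — and dominates the prediction comparison,
while the down-DEG tumor mean (unrelated to the planted hazard) trails.
All result tables are written as TSV under `out_dir`, and a second run
with the same configuration reproduces them byte-for-byte
(`output_checksums()`).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/agesurv run --out agesurv_out
Rscript inst/cli/agesurv deg --normal N.tsv --tumor T.tsv --out deg_out
```

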