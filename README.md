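# tensoromics

Multi-omics tensor fusion and survival risk stratification in R.

Cancer cohorts are profiled on several molecular assays at once — somatic
copy-number variation, DNA methylation, miRNA and RNA-seq — with feature
counts ranging from tens to hundreds of thousands per assay. `tensoromics`
integrates such a cohort into one low-dimensional patient representation and
asks whether it separates patients into survival risk groups, and which
biomarkers drive the separation. It is aimed at computational biologists who
have per-assay expression/abundance tables plus a clinical table with
overall-survival times.

## Method

1. **Preprocess** — align samples across assays, split 70/30 train/test,
   impute missing entries with train-fitted feature means, min-max scale
   per feature: `x' = (x − min) / (max − min)`.
2. **Compress** — one dense autoencoder per assay (ReLU hidden layers in a
   halving chain capped at 1024 nodes, linear bottleneck, sigmoid output;
   Adam, lr 0.001, 10 epochs, batch 128; bottleneck width selected by 10-fold
   CV over {64, 128, 256, 512}).
3. **Fuse** — split each latent block into chunks of the minimum block width
   *K* and stack all chunks into a tensor *X* (patients × slices × *K*);
   e.g. widths 256/128/512/256 fuse into 9 slices of 128.
4. **Decompose** — CANDECOMP/PARAFAC by regularized alternating least squares:

   *X* ≈ Σᵣ λᵣ · *A*ᵣ ∘ *B*ᵣ ∘ *C*ᵣ,  r = 1..R

   with an L1 soft-threshold on each factor update, the rank *R* chosen by
   the core consistency diagnostic (CORCONDIA ≥ 90).
5. **Stratify & explain** — hierarchical clustering of the patient-mode
   scores *A* (Canberra or Chebyshev distance, Ward linkage), Kaplan–Meier
   curves, log-rank test and univariate Cox hazard ratio per partition;
   tumor-purity classification (threshold 0.7) from the patient scores; and
   Kernel/Gradient SHAP attribution of latent coordinates back to features,
   with hypergeometric fold-enrichment statistics for annotated gene sets.

A synthetic-cohort generator (`generate_cohort()`) plants a latent risk
program that drives both the omics values and exponential
proportional-hazards survival, so the whole chain is testable without
downloads.

## Worked example

```r
library(tensoromics)

co <- generate_cohort(cohort_spec(
  n_samples = 300, assay_dims = c(snv = 32, mirna = 128, rna = 256, meth = 512),
  latent_dim = 4, risk_effect = 1.1, purity_effect = 2, seed = 42))

cfg <- pipeline_config(assays = co$assays, clinical = co$clinical,
                       latent_dims = 16, cp_rank = 3,
                       purity_models = c("logistic", "random_forest"),
                       seed = 42)
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   samples: 300 (train 210 / test 90)
#>   tensor: train 210x4x16, test 90x4x16
#>   CP rank 3: MSE train 0.06325 / test 0.06192
#>   log-rank p: train 1.154e-20 / test 3.498e-09

glance(res$stratification$test$fit)
#> # A tibble: 1 × 6
#>   logrank_chisq     logrank_p cox_hr cox_ci_low cox_ci_high n_groups
#>           <dbl>         <dbl>  <dbl>      <dbl>       <dbl>    <int>
#> 1          34.9 0.00000000350   5.48       2.95        10.2        2

res$purity
#> # A tibble: 2 × 4
#>   model         accuracy macro_f1 weighted_f1
#>   <chr>            <dbl>    <dbl>       <dbl>
#> 1 logistic         0.856    0.822       0.853
#> 2 random_forest    0.856    0.826       0.855
```

Reading the output: the four assays were compressed to 16 latent features
each and fused into a 210 × 4 × 16 training tensor; the rank-3 CP model
reconstructs it with mean squared error 0.063. Clustering the test-partition
patient scores into two groups separates survival with log-rank
p = 3.5 × 10⁻⁹ and a high-vs-low hazard ratio of 5.5 — the pipeline
recovered the planted risk program. The purity classifiers, trained on
training-partition patient scores projected into the same factor space,
label high/low purity test patients with 86% accuracy.

Every result type has `tidy()` / `glance()` methods and an `autoplot()`:
KM curves (`autoplot(res$stratification$test$fit)`), CP slice loadings
(`autoplot(res$cp$train)`), training loss (`autoplot(res$models$rna)`),
SHAP rankings (`autoplot(res$shap$snv$attribution)` when the explain stage
is enabled via `n_explain`).

A thin command-line wrapper over `run_pipeline()` is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --config config.yaml --outdir run1 --seed 7
```

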