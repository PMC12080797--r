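# survae

Progression-free survival (PFS) prediction from high-dimensional gene
expression, for analysts working with oncology trial cohorts where a
patient-by-gene expression matrix (thousands of genes, a few hundred
patients) is paired with right-censored survival labels.

The pipeline compresses expression profiles with regularized autoencoders —
denoising, sparse (Bernoulli-KL), variational (Gaussian or exponential
prior), and their combinations, in tabular form or attributed to a
protein–protein interaction network — then models survival on the latent
features:

- **Cox proportional hazards with elastic net.** With standardized latent
  covariates `X`, the fit minimizes the negative mean partial
  log-likelihood (Breslow tie handling) plus
  `λ[α‖β‖₁ + (1−α)/2‖β‖₂²]`, `α = 0.5` by default, with `λ` chosen by grid
  search over 50 values in `[1e-4, 1e-2]` scored by IPCW concordance.
- **Breslow baseline hazard** `Ĥ₀(t) = Σ_{t_k ≤ t} d_k / Σ_{j∈R(t_k)}
  exp(X_j β̂)`, giving per-patient survival curves
  `S(t|x) = exp(−Ĥ₀(t) e^{xβ̂})`.
- **PFS as the area under the survival curve** up to the training
  follow-up horizon (exact rectangle sum on the step function).
- **Evaluation**: reconstruction error, PFS mean squared error, Uno-style
  IPCW concordance, mean cumulative/dynamic time-dependent AUC, and the
  overestimation percentage.
- **Interpretability**: the five latent features with the largest absolute
  Cox coefficients are traced to genes by normalized mutual information
  (equal-frequency binning, `I/√(H·H)` scaling), aggregated across folds
  into a gene-frequency table.

A synthetic-cohort generator (`cohort_spec()`, `simulate_cohort()`)
produces expression with known nonlinear latent programs, histology
covariates, Weibull proportional-hazards event times with calibrated
uniform censoring, a scale-free interactome, and gene–disease tables — so
every stage runs and is tested fully offline. See the methods vignette
(`vignettes/latent-survival-methods.Rmd`) for the model details and design
rationale.

## Worked example

Simulate a cohort, run the cross-validated sparse-autoencoder pipeline and
the PCA baseline, and compare:

```r
library(survae)

spec <- cohort_spec(n_patients = 600, n_genes = 200, n_latent_true = 6,
                    beta_true = c(1, -1, 0.5, 0, 0, 0),
                    frac_uninformative = 0.3, censor_rate_target = 0.45,
                    seed = 101)
cohort <- simulate_cohort(spec)

report <- run_cross_validation(
  cohort$expression, cohort$histology, cohort$labels,
  n_folds = 2, latent_dim = 8, penalties = "sparse",
  ae_options = list(learning_rate = 3e-3, epochs = 300, lr_decay_every = 75),
  seed = 101
)
report
#> Cross-validated survival pipeline (autoencoder, L = 8, 2 folds)
#>   penalties: sparse
#>   reconstruction         0.1442 +/- 0.0394
#>   pfs_mse                6.7717 +/- 0.7770
#>   mean_auc               0.8172 +/- 0.0118
#>   overestimation_pct    74.1667 +/- 1.1785
#>   ipcw_concordance       0.7543 +/- 0.0040
```

Reading the output: the autoencoder reconstructs held-out expression with a
summed-over-genes MSE of 0.14 on the `[0,1]`-normalized scale; predicted
PFS deviates from the observed times by 6.8 (squared trimesters); risk
scores rank patients well (mean time-dependent AUC 0.82, IPCW concordance
0.75 against a 0.5 chance level); and predictions overestimate observed
times for ~74% of patients — the expected bias of the area-under-survival
construction when curves rarely reach zero within follow-up.

```r
baseline <- pca_baseline(cohort$expression, cohort$histology, cohort$labels,
                         n_folds = 2, latent_dim = 8, seed = 101)
mean(report$folds$reconstruction)    #> 0.144156
mean(baseline$folds$reconstruction)  #> 0.177579
```

The nonlinear compression out-reconstructs the rank-8 linear projection on
this six-program cohort. `tidy()`, `glance()` and `autoplot()` methods are
available on fits, reports and curves, and
`run_cross_validation(..., attribution = TRUE)` adds the per-fold gene
attribution and frequency table.

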