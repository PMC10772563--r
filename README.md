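# ecgsurv

Dynamic prediction of malignant ventricular arrhythmia risk from
longitudinally collected six-lead ECGs, for biostatisticians and
cardiology researchers working with implantable cardioverter-defibrillator
(ICD) cohorts.

Risk stratification for ventricular arrhythmias usually relies on static
baseline measurements, yet the arrhythmogenic substrate — and its trace in
the surface ECG — evolves over follow-up. `ecgsurv` implements a two-stage
dynamic model over routinely collected limb-lead ECGs:

1. **Representation learning.** Each recording is filtered
   (Savitzky–Golay smoothing; low-resolution cosine-series baseline-wander
   removal), R-peak aligned, beat-averaged into per-lead mean-beat
   templates normalised to [0, 1], and compressed by a β-VAE into 16
   latent variables AE0…AE15. The training loss is the ELBO,
   `L = MSE(x, x̂) + β · KL(q(z|x) ‖ N(0, I))`, with
   `KL = −½ Σᵢ (1 + log σᵢ² − μᵢ² − σᵢ²)`.
2. **Dynamic survival modelling.** Follow-up is restructured into 90-day
   person-period intervals (CPIUs) with risk time τ, event indicator d,
   and last-value-carried-forward latent features plus static baseline
   covariates. A random forest grown with the Poisson log-likelihood
   splitting criterion
   `gain = Σ_c D_c log(D_c/T_c) − D log(D/T)`
   (D = events, T = risk time; no proportional-hazards assumption) stores
   Bayes-smoothed leaf hazards `λ = (D + a)/(T + b)`, `a = r₀·b`, and
   predicts per-interval event probabilities `p = 1 − exp(−λτ)`. A
   baseline-frozen *static* comparator runs through identical machinery,
   isolating the contribution of the time-varying ECG features.

Evaluation uses time-specific ROC analysis (per-interval AUROC and its
unweighted mean ± sd over the 48-month horizon), decile calibration,
500-iteration patient-level bootstrap CIs, permutation feature importance
and subgroup (fairness) summaries. Interpretability comes from latent
factor traversal (decoding a reference code with one dimension swept
across its cohort percentiles) and latent–feature correlation. A
time-varying Cox model on the same person-period rows is included via
`survival::coxph()`.

Because the motivating clinical registry is not publicly deposited, the
package ships a seed-reproducible synthetic cohort generator (Gaussian-sum
beat model with derived limb leads, per-patient T-wave morphology drift,
baseline covariates with injected missingness, events from a
piecewise-constant hazard tied to the drifting morphology) so the entire
pipeline is testable end to end with planted, recoverable structure.

## Worked example

```r
library(ecgsurv)
library(dplyr)

# 1. a synthetic ICD cohort with drifting T-wave morphology
cohort <- simulate_cohort(300, seed = 1)
cohort
#> <synthetic_cohort> 300 patients, 2272 ECG visits, 80 events (seed 1)

# 2. beat templates for every visit; pretrain a VAE on a general pool,
#    then fine-tune on this cohort's templates
templates <- cohort_templates(cohort, method = "analytic", seed = 2)
X <- template_matrix(templates)

pool <- random_morphology(1500, seed = 4)
set.seed(5)
Xpool <- t(sapply(pool, function(p)
  template_vector(template_from_params(p, residual_sd = 0.01))))

vae <- build_vae(ncol(X), hidden = c(128, 64, 32), beta = 1, seed = 3) |>
  train_vae(Xpool, epochs = 60, batch_size = 128, seed = 4, warmup = 15) |>
  train_vae(X, epochs = 25, batch_size = 128, seed = 5, warmup = 0,
            mode = "finetune")
glance(vae)[, c("n_parameters", "epochs", "train_loss", "val_loss")]
#> # A tibble: 1 × 4
#>   n_parameters epochs train_loss val_loss
#>          <int>  <int>      <dbl>    <dbl>
#> 1       292346     85     0.0108   0.0113

# 3. latent codes -> 90-day person-period rows with LVCF features
codes <- encode_templates(vae, templates)
split <- split_cohort(cohort$outcomes$patient_id, seed = 6,
                      stratify = cohort$outcomes$event)
feats <- impute_and_encode(cohort$baseline, train_ids = split$train, seed = 7)
rows <- build_cpius(cohort$outcomes, codes, baseline_features = feats)
rows |> select(patient_id, k, tau, d, ecg_age, AE0, AE1) |> head(4)
#> # A tibble: 4 × 7
#>   patient_id     k   tau     d ecg_age   AE0   AE1
#>   <chr>      <int> <dbl> <int>   <dbl> <dbl> <dbl>
#> 1 P00001         0    90     0       0 0.259 -2.68
#> 2 P00001         1    90     0      90 0.259 -2.68
#> 3 P00001         2    90     0      55 0.238 -2.76
#> 4 P00001         3    90     0     145 0.238 -2.76

# 4. dynamic forest vs baseline-frozen static comparator
train <- rows |> filter(patient_id %in% split$train)
test  <- rows |> filter(patient_id %in% split$test)
dynamic <- fit_hazard_forest(train, n_trees = 150, min_events = 15, seed = 8)
static  <- fit_static_model(train, n_trees = 150, min_events = 15, seed = 8)

# 5. time-dependent evaluation on the held-out patients
evaluate_model(dynamic, test, n_boot = 200, seed = 9)
#> <eval_report> dynamic model: mean time-varying AUROC 0.655 +/- 0.291 over 5 valid intervals (horizon 16)
#>   bootstrap 95% CI: [0.493, 0.894] (200 resamples)
evaluate_model(static, test)
#> <eval_report> static model: mean time-varying AUROC 0.543 +/- 0.239 over 5 valid intervals (horizon 16)
```

At this demonstration scale (300 patients, 80 events) the intervals are
sparse and the AUROCs noisy; the dynamic model's advantage over the static
one (0.655 vs 0.543 here) becomes systematic at study scale — at 1,000
patients the gap exceeds 0.03 in essentially every paired replicate, while
disabling the morphology drift removes it. `autoplot()` on an
`eval_report`, `plot_calibration()`, `plot_importance()` and `autoplot()`
on a `traverse_latent()` result give the standard figures;
`tidy()`/`glance()` methods return tibbles throughout.

The full experiment — simulate → preprocess → train-vae → encode →
build-cpiu → fit → evaluate → interpret — can also be driven from one
configuration object with hash-chained stage manifests:

```r
run_pipeline(default_config(), "artifacts/")
```

or from a shell via `inst/scripts/run_pipeline.R`.

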