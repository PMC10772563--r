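---
title: "Dynamic arrhythmia risk from longitudinal ECGs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic arrhythmia risk from longitudinal ECGs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgsurv)
```

## The problem

Patients carrying an implantable cardioverter-defibrillator (ICD) remain at
risk of malignant ventricular arrhythmias (sustained VT/VF), and that risk
is not static: the arrhythmogenic substrate evolves over months to years,
and the surface ECG — recorded routinely at follow-up visits — carries a
trace of that evolution. `ecgsurv` implements a two-stage dynamic risk
model:

1. an **unsupervised stage** that compresses each six-limb-lead ECG into 16
   latent variables (`AE0` … `AE15`) with a β-variational autoencoder
   trained on mean-beat templates, and
2. a **supervised stage** that arranges follow-up into 90-day
   person-period intervals (counting-process information units, CPIUs) and
   fits a Poisson-splitting random forest whose leaves hold Bayes-smoothed
   hazard rates, giving each patient an updated piecewise-constant hazard
   as new ECGs arrive.

A *static* comparator uses the identical machinery with every latent
feature frozen at its day-0 value, so any performance difference isolates
the value of the time-varying ECG information.

Because the clinical cohort that motivated this design is not publicly
deposited, the package ships a fully specified synthetic cohort generator
with planted, recoverable structure; every claim the test suite makes is a
property of the method demonstrated on that generator.

## The synthetic cohort generator

**Beat model.** A heartbeat in leads I and II is a sum of five Gaussian
waves (P, Q, R, S, T), each parameterised by amplitude (mV), center
(seconds relative to the R peak) and width (seconds). The four remaining
limb leads are linear in I and II (Einthoven/Goldberger):
`III = II − I`, `aVR = −(I+II)/2`, `aVL = I − II/2`, `aVF = II − I/2`,
applied *before* noise, so the lead identities hold exactly on noiseless
output. Records add per-lead white noise and a low-frequency (≤ 0.5 Hz)
cosine baseline wander. This Gaussian-sum design (a simplified ECGSYN-style
model) was chosen because every morphological feature has a known ground
truth, enabling parameter-recovery tests; it does not attempt a
physiologically faithful dipole simulation, arrhythmic waveforms, or
precordial leads.

**Population and follow-up.** Baseline covariates mirror a large
contemporary ICD cohort: 74.5% male, 60.5% primary prevention, LVEF classes
22.8/16.6/60.6%, 41.6% ischaemic cardiomyopathy, age 61.7 ± 13.9 years,
electrolyte and creatinine moments to match, 10% missingness injected
completely at random into laboratory values, and one designated column
(`nt_probnp`, 35% missing) that exercises the ≥ 30% exclusion rule.
Missing-completely-at-random is the simplest mechanism consistent with the
imputation stage and is a known simplification. Visits occur at day 0
(guaranteed) and then at gaps ~ Normal(180, 45²) days truncated at 30,
reflecting bi-yearly follow-up; the true visit intensity of any given
clinic is not a claim of this generator.

**Morphology drift.** The lead-II T-wave amplitude, T width and heart rate
follow Gaussian random walks on the 90-day grid (defaults 0.08 mV, 0.002 s
and 2 bpm per step). The T-amplitude step was chosen so that over 48 months
a patient's T wave can flatten or invert — the kind of repolarisation
change the dynamic model is meant to exploit. Visits observe the walk at
the grid point in force on the visit day.

**Events.** The per-day hazard in interval *k* is
`λ = λ₀ · exp(β_T (T_amp_k − 0.35) + 0.6·priorVTVF + 0.5·LVEF≤35)` with
`β_T = −10` per mV and `λ₀ = 3.5×10⁻⁵`/day, giving a ~28% cumulative event
fraction over the 48-month horizon (matching the event rate such ICD
cohorts report). Event probability within an interval is
`1 − exp(−λ·len)`, with the event day uniform inside the triggering
interval — exactly the piecewise-constant hazard family the estimator
assumes. The drift-disabled control condition uses `λ₀ = 1.3×10⁻⁴`/day so
that both arms share the same event fraction (without drift the log-normal
Jensen inflation of the marginal rate disappears).

## ECG preprocessing

Recordings at 500 Hz are decimated by 2 after an anti-alias FIR low-pass;
250 Hz records pass through. Each lead is smoothed with a Savitzky–Golay
filter (window 15 samples = 60 ms, polynomial order 3 — unspecified in the
source methodology, configurable here) and detrended by subtracting a
least-squares cosine-series fit with frequencies `k/(2·duration)` up to
0.7 Hz. R peaks are detected on lead II by band-passing (5–20 Hz,
zero-phase Butterworth), squaring the first difference, smoothing the
energy and picking one peak per supra-threshold run with a 0.24 s
refractory period, then refining to the local signal maximum; any detector
meeting the ±40 ms / 0.99 recall-precision tolerances would be conformant.
Beats are averaged on a fixed window of 0.25 s before and 0.45 s after the
R peak (L = 175 samples at 250 Hz) — at least three full-window beats are
required — and each lead is min–max normalised to [0, 1]. A constant lead
maps to all-0.5 by convention. When several ECGs share a calendar day only
the first is kept. No quality gating is applied: templates from noisy
records stay in, mirroring a pipeline with no visual inspection.

The VAE consumes the six leads concatenated in the fixed order I, II, III,
aVR, aVL, aVF (input dimension 1050); single-lead mode uses the same code
path with the lead-II block only (input dimension 175).

For large simulation studies the generator can also emit templates
*analytically* — evaluating the Gaussian-sum model directly on the template
grid with neighbouring-beat spill-over and a small residual noise term
(default 0.01 mV, roughly what survives ten-beat averaging). The full
raw-signal path and the analytic path agree to within a few percent RMSE on
noiseless input; the preprocessing tests exercise the full path, and the
large replicated experiments use the analytic path for speed. The problem
sizes used throughout (5,000-template pretraining pool, cohorts of
500–2,000 patients, 150–300 trees) are the package's study-scale choices.

## The β-VAE

The encoder is three affine + ReLU layers (default widths 256, 128, 64 in
the shipped experiments; the constructor default is 512, 256, 128 and all
widths are configurable) feeding two affine heads for the posterior mean
and log-variance of a 16-dimensional Gaussian; a reparameterised sample
`z = μ + σ·ε` feeds the mirrored three-layer decoder with a linear output.
`vae_loss()` reports the mean-squared-error reconstruction term, the KL
divergence `−½Σ(1 + log σ² − μ² − σ²)` and `total = recon + β·KL`.

Two numerical choices matter:

* **Objective scaling.** During optimisation the KL term is weighted by
  `β / input_dim` — equivalently, the reconstruction is the summed squared
  error and the whole objective is divided by the input dimension. This is
  the standard Gaussian-decoder ELBO normalisation; without it the KL term
  dominates by a factor of the input dimension and the posterior collapses
  at any β.
* **KL warm-up.** The KL weight is annealed linearly from 0 over the first
  ~20 epochs. Without warm-up the optimiser settles into posterior collapse
  (all posteriors at the prior) before the decoder learns to use the
  latent space.

With these, β = 1 (the default; β is exposed for disentanglement studies)
yields, after convergence, per-dimension posterior-mean averages within
±0.05 of zero and an aggregate-posterior standard deviation
(`sqrt(var(μ_j) + mean(σ²_j))`) within a few percent of 1 — the latent
space is properly regularised toward its prior — at a held-out
reconstruction correlation of ~0.95 on pool templates.

**Pretrain, then fine-tune.** The workflow trains first on a large pool of
randomised morphologies (emulating a general hospital ECG database,
including a continuous spectrum of T-wave amplitudes down to inverted T)
and then fine-tunes on the study cohort's own templates. Fine-tuning is not
cosmetic: cohort templates with strongly drifted or inverted T waves are
out of distribution for a pool-only model, in which case T-amplitude
information lands on latent dimensions the decoder barely uses and factor
traversal fails to localise. After fine-tuning, the latent dimension most
correlated with the generator's T amplitude is an active one and its
traversal perturbs the T-wave window several-fold more than the QRS
window. Training uses Adam with minibatches, a 10% validation split (by
rows, or by patients when supplied) and early stopping on the validation
objective; downstream features are always the posterior means μ, never
Monte-Carlo samples, so encoding is deterministic.

## Person-period restructuring (CPIUs)

Follow-up is cut into 90-day intervals. Each row carries the risk time τ
(`0 < τ ≤ 90`), the event indicator (1 only on an event patient's final
row), and the features in force at the interval start: the latent code of
the most recent ECG with `day ≤ 90k` (last value carried forward, no
within-interval look-ahead) plus static baseline covariates. An event or
censoring falling exactly on a boundary closes the previous interval — no
zero-length rows. Risk time is conserved exactly: each patient's τ values
sum to their follow-up days.

Baseline covariates are prepared by a leakage-aware preprocessor: columns
with ≥ 30% missingness on the training fold are dropped; the rest are
imputed by iterative random-forest imputation (models fit on training-fold
rows only, then applied everywhere); categoricals are one-hot encoded and
numerics z-scored with training-fold statistics. Patients — never rows —
are assigned to the 80:20 train/test split, optionally stratified on the
event indicator.

## The Poisson-splitting hazard forest

Each tree is grown on a patient-level bootstrap (all of a patient's rows
enter together — row-level bootstrap would leak within-patient
information). At each node `mtry` candidate features are examined; the
chosen split maximises the Poisson log-likelihood gain
`Σ_c D_c log(D_c/T_c) − D log(D/T)` (with `0·log 0 ≡ 0`), where `D` is the
event count and `T` the risk time; this criterion needs no
proportional-hazards assumption. A split is admissible only if both
children retain at least `min_events` events and `min_obs` rows and
positive risk time. Leaves store the Bayes-smoothed rate
`λ = (D + a)/(T + b)` with `b = 90` days of pseudo-risk-time (one CPIU) and
`a = r₀·b`, `r₀` being the tree's root event rate, so the prior mean is
the marginal hazard. Prediction averages leaf rates across trees;
`p = 1 − exp(−λ·τ)` converts to an interval event probability.
Hyperparameters (trees, mtry, minimum terminal events) can be tuned by
patient-level 5-fold cross-validation on the mean time-varying AUROC, with
ties broken toward smaller forests; the default grid is
trees {100, 300} × mtry {√p, p/3} × events {5, 15}.

One behaviour worth knowing: with per-patient constant covariates, very
small leaves systematically *inflate* predicted hazards, because split
selection concentrates eventful (hence short-follow-up) patients into
high-rate leaves that row-uniform averaging over-weights. Discrimination
(AUROC ranking) is robust to this, but absolute rate recovery is not — so
the rate-recovery analyses in this package use `mtry = p` and
`min_events = 60`, and measure recovery on an independent test cohort,
never in-bag. This is documented measurement design, not tuning.

The time-varying Cox model (`fit_time_varying_cox()`) converts CPIUs to
counting-process `(start, stop, event)` form and delegates to
`survival::coxph()` — standard inference, not bespoke computation; hazard
ratios, 95% CIs and p-values come back as a tidy tibble and
non-convergence is surfaced as a warning attribute.

## Evaluation

The **time-specific AUROC** of interval *k* is the Mann–Whitney
probability `P(p_case > p_control) + ½P(tie)` over the at-risk rows of
that interval — "time-specific" is read inside the CPIU framework;
incident/dynamic AUROC over continuous time is out of scope. Intervals
with fewer than 2 events or 2 non-events are flagged and excluded; the
**mean time-varying AUROC** is the unweighted mean (± sd) of the valid
intervals within the 16-interval (48-month) horizon. Calibration uses the
decile method with tied predictions kept in one group. Confidence
intervals come from a 500-iteration patient-level bootstrap (unique
patients drawn with replacement, all their rows together). Permutation
importance shuffles one feature column across the test rows, recomputes
the mean time-varying AUROC, and averages the drop over five repeats;
subgroup performance recomputes the summary inside clinically defined
strata (sex, ischaemic status, prevention indication, LVEF class).

On the default generator the dynamic forest reaches a mean time-varying
AUROC around 0.72–0.75 against 0.45–0.60 for the baseline-frozen static
model — the separation direction the method exists to demonstrate — and
with drift disabled the two models are equivalent within sampling noise.
Because the per-replicate sampling noise of an AUROC gap at 1,000 patients
is ~±0.035, the no-drift equivalence claim is asserted on the *mean* gap
over eight paired replicates of 2,000 patients, not per replicate.

## Interpretability

Factor traversal decodes a reference latent vector (the element-wise
median of the cohort's posterior means — the reference is a documented
choice, as the underlying methodology does not state one) with one
dimension swept across its cohort 5/25/75/95th percentiles
(linear-interpolation quantiles), and maps `|reconstruction − reference|`
per sample — a heatmap of where in the beat that dimension acts. Latent
codes can also be correlated against any interpretable feature table;
here the generator's ground-truth parameters and simple template
measurements (QRS width by half-prominence crossing, R amplitude) stand in
for external human-interpretable ECG classifiers, whose trained weights
are out of scope.

## Pipeline

`run_stage()` / `run_pipeline()` orchestrate
simulate → preprocess → train-vae → encode → build-cpiu → fit → evaluate →
interpret against one artifact directory. Every stage writes a JSON
manifest with its configuration hash, seeds, input and output MD5 hashes
and row counts; re-running an unchanged stage is a no-op, and a missing
upstream artifact raises an error naming it. The whole experiment is a
deterministic function of the configuration and its seeds, and sensitivity
variants (single-lead VAE, alternative outcome tables) are configuration
diffs, not code changes.

## What passing tests do and do not show

The generator plants exactly the structure the model family assumes:
piecewise-constant hazards on the 90-day grid, log-linear covariate
effects, Gaussian-random-walk drift observed at visit days, and
morphology parameterised by a small number of factors. Passing tests
therefore demonstrate *method correctness and recoverability under the
assumed model*, including realistic nuisances the generator does include —
irregular visits, LVCF staleness, encoding noise, missing covariates,
administrative censoring. They do not demonstrate robustness to what it
excludes: ectopic or arrhythmic beats inside recordings, non-random
missingness, measurement artefacts beyond white noise and cosine wander,
competing mortality risk, or hazard mechanisms outside the assumed family.
Those remain the caveats any real-data application should carry.
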