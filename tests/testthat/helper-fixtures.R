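# Shared fixtures, built lazily once per test session.
#
# The "study" VAE mirrors the experiment workflow: pretrain on a large pool
# of randomised morphologies, then fine-tune on templates from a reference
# drifting cohort. Heavy acceptance tests share it through `study_vae()`.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# n x 1050 matrix of pool templates (fresh morphologies, light residual noise)
pool_templates <- function(n, seed) {
  pool <- random_morphology(n, seed = seed)
  set.seed(seed + 1L)
  t(vapply(pool, function(p)
    template_vector(template_from_params(p, residual_sd = 0.01)),
    numeric(1050)))
}

study_pool <- function() memo("study_pool", function() pool_templates(5000, 99))

study_vae <- function() memo("study_vae", function() {
  Xp <- study_pool()
  vae <- build_vae(ncol(Xp), hidden = c(256, 128, 64), beta = 1, seed = 7)
  vae <- train_vae(vae, Xp, epochs = 120, batch_size = 128, seed = 7,
                   warmup = 20, patience = 25)
  ref_co <- simulate_cohort(600, seed = 77)
  ref_tpl <- cohort_templates(ref_co, method = "analytic", seed = 78)
  train_vae(vae, template_matrix(ref_tpl), epochs = 40, batch_size = 128,
            seed = 8, warmup = 0, patience = 15, mode = "finetune")
})

# a small trained VAE for cheap unit tests (coarse reconstructions suffice)
tiny_vae <- function() memo("tiny_vae", function() {
  X <- pool_templates(400, 11)
  vae <- build_vae(ncol(X), hidden = c(64, 48, 32), beta = 1, seed = 3)
  train_vae(vae, X, epochs = 30, batch_size = 64, seed = 3, warmup = 10)
})

# lead-II T-peak and QRS windows implied by the generator's wave centers
T_WINDOW <- c(0.15, 0.40)
QRS_WINDOW <- c(-0.06, 0.06)

# true lead-II T amplitude per visit of a synthetic cohort
visit_t_amp <- function(cohort) {
  dplyr::tibble(
    patient_id = cohort$visits$patient_id,
    day = cohort$visits$day,
    t_amp = vapply(cohort$visits$params,
                   function(p) p$waves$II["T", "amplitude"], numeric(1)))
}

# one dynamic-vs-static replicate of the drift experiment; returns both
# mean time-varying AUROCs
dyn_static_replicate <- function(vae, r, drift = TRUE, n = 1000,
                                 n_trees = 150) {
  tc <- trajectory_config(step_sd = c(t_amp = if (drift) 0.08 else 0,
                                      t_width = if (drift) 0.002 else 0,
                                      heart_rate = if (drift) 2 else 0))
  hz <- hazard_spec(base_hazard = if (drift) 3.5e-5 else 1.3e-4)
  co <- simulate_cohort(n, seed = 1000 + r, traj_cfg = tc, spec = hz)
  tpl <- cohort_templates(co, method = "analytic", seed = 2000 + r)
  codes <- encode_templates(vae, tpl)
  sp <- split_cohort(co$outcomes$patient_id, seed = 3000 + r,
                     stratify = co$outcomes$event)
  feats <- impute_and_encode(co$baseline, train_ids = sp$train,
                             seed = 4000 + r)
  rows <- build_cpius(co$outcomes, codes, baseline_features = feats)
  tr <- rows[rows$patient_id %in% sp$train, ]
  te <- rows[rows$patient_id %in% sp$test, ]
  dyn <- fit_hazard_forest(tr, n_trees = n_trees, min_events = 15,
                           seed = 5000 + r)
  sta <- fit_static_model(tr, n_trees = n_trees, min_events = 15,
                          seed = 5000 + r)
  c(dynamic = mean_time_varying_auroc(predict_hazard(dyn, te))$mean,
    static = mean_time_varying_auroc(predict_hazard(sta, te))$mean)
}

# two-rate cohort for hazard-recovery checks: binary covariate with true
# hazards 0.001 vs 0.01 per day plus two pure-noise covariates
two_rate_cohort <- function(seed, n = 2000, horizon = 1440) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  et <- rexp(n, ifelse(x == 1, 0.01, 0.001))
  oc <- dplyr::tibble(
    patient_id = sprintf("S%d_%05d", seed, seq_len(n)),
    follow_up_days = pmin(ceiling(et), horizon),
    event = as.integer(et <= horizon))
  cd <- dplyr::tibble(patient_id = oc$patient_id, day = 0, xbin = x,
                      noise1 = rnorm(n), noise2 = rnorm(n))
  build_cpius(oc, cd)
}
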