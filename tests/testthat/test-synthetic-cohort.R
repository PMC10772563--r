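test_that("baseline generation is seed-reproducible and matches configured prevalences", {
  a <- generate_baseline(100, seed = 7)
  b <- generate_baseline(100, seed = 7)
  expect_identical(a, b)

  one <- generate_baseline(1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_true(all(!is.na(one$age)))

  big <- generate_baseline(1000, seed = 11)
  expect_lt(abs(mean(big$sex == "male") - 0.745), 0.04)
  # designated high-missingness column exceeds the 30% exclusion threshold
  expect_gte(mean(is.na(big$nt_probnp)), 0.30)
  lab_miss <- mean(is.na(big$sodium))
  expect_gt(lab_miss, 0.05)
  expect_lt(lab_miss, 0.15)

  expect_error(generate_baseline(0), "positive")
})

test_that("morphology parameter invariants are enforced", {
  expect_error(morphology_params(heart_rate = 200), "heart_rate")
  w <- default_wave_sets()
  w$II["T", "width"] <- -0.01
  expect_error(morphology_params(waves = w), "width")
  w <- default_wave_sets()
  w$II["R", "amplitude"] <- -1
  expect_error(morphology_params(waves = w), "R amplitude")
  w <- default_wave_sets()
  w$II["P", "center"] <- 0.1   # violates P < Q ordering
  expect_error(morphology_params(waves = w), "ordered")
})

test_that("synthetic leads satisfy the Einthoven/Goldberger identities exactly", {
  p <- morphology_params()
  rec <- synthesize_ecg(p, noise_sd = 0, wander_amp = 0)
  s <- rec$signal
  expect_equal(s["III", ], s["II", ] - s["I", ], tolerance = 1e-12)
  expect_equal(s["aVR", ], -(s["I", ] + s["II", ]) / 2, tolerance = 1e-12)
  expect_equal(s["aVL", ], s["I", ] - s["II", ] / 2, tolerance = 1e-12)
  expect_equal(s["aVF", ], s["II", ] - s["I", ] / 2, tolerance = 1e-12)
  expect_lt(max(abs(colSums(s[c("aVR", "aVL", "aVF"), ]))), 1e-12)

  # Goldberger values at a constructed sample: I = 0.5, II = 1.0
  expect_equal(unname(-(0.5 + 1.0) / 2), -0.75)
  expect_equal(unname(0.5 - 1.0 / 2), 0.0)
  expect_equal(unname(1.0 - 0.5 / 2), 0.75)

  expect_error(synthesize_ecg(p, fs = 300), "sampling rate")
})

test_that("a 60 bpm 10-second record contains 10 +/- 1 beats", {
  p <- morphology_params(heart_rate = 60)
  rec <- synthesize_ecg(p, duration = 10, noise_sd = 0, wander_amp = 0)
  peaks <- detect_r_peaks(rec$signal["II", ], rec$fs)
  expect_gte(length(peaks), 9)
  expect_lte(length(peaks), 11)
  expect_equal(length(true_r_times(p, 10)), 10)
})

test_that("morphology random walk has the prescribed degenerate and variance behaviour", {
  p <- morphology_params()
  cfg0 <- trajectory_config(step_sd = c(t_amp = 0, t_width = 0, heart_rate = 0))
  traj <- generate_trajectory(p, cfg0, seed = 5)
  t_amps <- vapply(traj$params, function(q) q$waves$II["T", "amplitude"],
                   numeric(1))
  expect_true(all(t_amps == t_amps[1]))

  # variance of the walk after 16 steps ~ 16 * s^2 (Monte Carlo)
  s <- 0.05
  cfg <- trajectory_config(step_sd = c(t_amp = s, t_width = 0, heart_rate = 0),
                           horizon = 17 * 90)
  finals <- vapply(seq_len(1000), function(i) {
    set.seed(i)
    w <- morphology_walk(p, cfg)
    w$t_amp[17]
  }, numeric(1))
  expect_lt(abs(var(finals) / (16 * s^2) - 1), 0.2)

  # short horizon with long visit gaps still yields the day-0 visit
  cfgs <- trajectory_config(horizon = 100, visit_gap_mean = 180)
  traj2 <- generate_trajectory(p, cfgs, seed = 2)
  expect_true(0 %in% traj2$day)
})

test_that("null hazard censors everyone at the horizon (flat survival)", {
  co <- simulate_cohort(
    60, seed = 4,
    spec = hazard_spec(base_hazard = 0, coefs = c(t_amp = 0),
                       baseline_coefs = c(prior_vtvf = 0)))
  expect_true(all(co$outcomes$event == 0L))
  expect_true(all(co$outcomes$follow_up_days == 1440))
  km <- survival::survfit(
    survival::Surv(co$outcomes$follow_up_days, co$outcomes$event) ~ 1)
  expect_true(all(km$surv == 1))
})

test_that("constant-hazard event times match the exponential mean", {
  n <- 2000
  bl <- generate_baseline(n, seed = 9)
  walks <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    dplyr::tibble(patient_id = bl$patient_id[i], k = 0:199,
                  day_start = (0:199) * 90, t_amp = 0.35, t_width = 0.045,
                  heart_rate = 60)))
  spec <- hazard_spec(base_hazard = 0.002, coefs = c(t_amp = 0),
                      baseline_coefs = c(prior_vtvf = 0))
  oc <- simulate_events(walks, bl, spec, horizon = 18000, seed = 12)
  expect_gt(mean(oc$event), 0.999)
  expect_lt(abs(mean(oc$event_day, na.rm = TRUE) - 500), 40)
})

test_that("stronger T-amplitude dependence raises event incidence monotonically", {
  frac <- vapply(c(-5, -10), function(cf) {
    co <- simulate_cohort(400, seed = 21,
                          spec = hazard_spec(coefs = c(t_amp = cf)))
    mean(co$outcomes$event)
  }, numeric(1))
  expect_gt(frac[2], frac[1])
})

test_that("cohorts are deterministic and respect risk-set consistency", {
  a <- simulate_cohort(40, seed = 31)
  b <- simulate_cohort(40, seed = 31)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$visits$day, b$visits$day)

  fup <- setNames(a$outcomes$follow_up_days, a$outcomes$patient_id)
  expect_true(all(a$visits$day <= fup[a$visits$patient_id]))
  day0 <- tapply(a$visits$day, a$visits$patient_id, min)
  expect_true(all(day0 == 0))
  expect_false(anyDuplicated(a$outcomes$patient_id) > 0)
  ev <- a$outcomes[a$outcomes$event == 1L, ]
  expect_true(all(ev$event_day <= ev$follow_up_days))
})

test_that("cohort export writes the documented plain-text artifacts", {
  co <- simulate_cohort(10, seed = 41)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "baseline.csv")))
  expect_true(file.exists(file.path(dir, "outcomes.csv")))
  man <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"))
  expect_equal(man$n_patients, 10)
  expect_equal(man$seed, 41)
})
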