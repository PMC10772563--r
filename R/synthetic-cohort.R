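#' Beat morphology parameters for the Gaussian-sum ECG model
#'
#' A heartbeat in leads I and II is modelled as a sum of five Gaussian waves
#' (P, Q, R, S, T), each with an amplitude (mV), a center (seconds relative to
#' the R peak) and a width (seconds). The remaining limb leads are derived
#' from I and II through the Einthoven/Goldberger identities, so the two wave
#' sets fully determine the noiseless six-lead signal. The T-inversion factor
#' multiplies the T amplitude in both leads, so a negative value flips the
#' T wave.
#'
#' @param heart_rate Heart rate in beats per minute, must lie in `[30, 180]`.
#' @param t_inversion Dimensionless factor applied to both T amplitudes.
#' @param waves Named list with elements `I` and `II`, each a 5 x 3 numeric
#'   matrix with rows `P,Q,R,S,T` and columns `amplitude,center,width`.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(heart_rate = 60, t_inversion = 1,
                              waves = default_wave_sets()) {
  stopifnot(is.list(waves), all(c("I", "II") %in% names(waves)))
  for (ld in c("I", "II")) {
    w <- waves[[ld]]
    if (!is.matrix(w) || nrow(w) != 5L || ncol(w) != 3L)
      stop("wave set for lead ", ld, " must be a 5x3 matrix", call. = FALSE)
    dimnames(w) <- list(c("P", "Q", "R", "S", "T"),
                        c("amplitude", "center", "width"))
    if (any(w[, "width"] <= 0))
      stop("wave widths must be positive", call. = FALSE)
    if (w["R", "amplitude"] <= 0)
      stop("R amplitude must be positive", call. = FALSE)
    if (any(diff(w[, "center"]) <= 0))
      stop("wave centers must be ordered P < Q < R < S < T", call. = FALSE)
    waves[[ld]] <- w
  }
  if (!is.numeric(heart_rate) || heart_rate < 30 || heart_rate > 180)
    stop("heart_rate must lie in [30, 180]", call. = FALSE)
  structure(list(heart_rate = heart_rate, t_inversion = t_inversion,
                 waves = waves),
            class = "morphology_params")
}

#' @rdname morphology_params
#' @export
default_wave_sets <- function() {
  II <- rbind(P = c(0.15, -0.220, 0.025),
              Q = c(-0.10, -0.035, 0.010),
              R = c(1.00, 0.000, 0.012),
              S = c(-0.20, 0.040, 0.012),
              T = c(0.35, 0.260, 0.045))
  I <- rbind(P = c(0.08, -0.220, 0.025),
             Q = c(-0.06, -0.035, 0.010),
             R = c(0.60, 0.000, 0.012),
             S = c(-0.12, 0.040, 0.012),
             T = c(0.22, 0.260, 0.045))
  colnames(I) <- colnames(II) <- c("amplitude", "center", "width")
  list(I = I, II = II)
}

#' Draw randomised beat morphologies
#'
#' Samples `n` `morphology_params` objects around the default wave sets:
#' log-normal amplitude jitter, normal width/center jitter, uniform heart
#' rate, and occasional T-wave inversion. Used to build the pretraining pool
#' and per-patient baseline morphologies.
#'
#' @param n Number of morphologies to draw.
#' @param seed Integer seed.
#' @param amp_jitter_sd SD of log-amplitude jitter.
#' @param width_jitter_sd SD of multiplicative log-width jitter.
#' @param hr_range Uniform heart-rate range (bpm).
#' @param p_t_inversion Probability of drawing from the low/inverted-T
#'   component; the T-scale factor is a two-component normal mixture
#'   (mostly upright T around 1, a minority flat-to-inverted around -0.5),
#'   giving a continuous spectrum of T morphologies as seen in routine
#'   hospital ECG databases.
#' @return List of `morphology_params`.
#' @export
random_morphology <- function(n, seed = 1L, amp_jitter_sd = 0.15,
                              width_jitter_sd = 0.10, hr_range = c(48, 110),
                              p_t_inversion = 0.15) {
  stopifnot(n >= 1)
  set.seed(seed)
  base <- default_wave_sets()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    waves <- base
    # shared center jitter keeps the P<Q<R<S<T ordering intact
    c_shift <- c(P = rnorm(1, 0, 0.015), Q = 0, R = 0, S = 0,
                 T = rnorm(1, 0, 0.020))
    for (ld in c("I", "II")) {
      w <- waves[[ld]]
      w[, "amplitude"] <- w[, "amplitude"] * exp(rnorm(5, 0, amp_jitter_sd))
      w[, "width"] <- w[, "width"] * exp(rnorm(5, 0, width_jitter_sd))
      w[, "center"] <- w[, "center"] + c_shift
      waves[[ld]] <- w
    }
    hr <- runif(1, hr_range[1], hr_range[2])
    tinv <- if (runif(1) < p_t_inversion) rnorm(1, -0.5, 0.35)
    else rnorm(1, 1, 0.30)
    out[[i]] <- morphology_params(heart_rate = hr, t_inversion = tinv,
                                  waves = waves)
  }
  out
}

# sum-of-Gaussians value of one lead at times tt (seconds relative to the
# R peak), including the two neighbouring beats of the periodic train
gaussian_lead <- function(tt, wave, t_inversion = 1, period = NULL) {
  amps <- wave[, "amplitude"]
  amps["T"] <- amps["T"] * t_inversion
  offs <- if (is.null(period)) 0 else c(-period, 0, period)
  y <- numeric(length(tt))
  for (off in offs) {
    for (w in rownames(wave)) {
      y <- y + amps[[w]] *
        exp(-((tt - off - wave[w, "center"])^2) / (2 * wave[w, "width"]^2))
    }
  }
  y
}

#' Construct an ECG recording object
#'
#' @param signal Numeric leads x samples matrix (mV) with row names giving
#'   the lead labels.
#' @param fs Sampling rate in Hz (250 or 500).
#' @param patient_id Patient identifier.
#' @param day Recording day (days since device implantation).
#' @param seq Within-day acquisition order (used by same-day deduplication).
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(signal, fs, patient_id = NA_character_, day = 0,
                          seq = 1L) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  if (!fs %in% c(250, 500))
    stop("unsupported sampling rate: ", fs, " (must be 250 or 500 Hz)",
         call. = FALSE)
  structure(list(patient_id = patient_id, day = day, seq = seq, fs = fs,
                 leads = rownames(signal), signal = signal),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> patient %s, day %s: %d leads x %d samples @ %g Hz\n",
              x$patient_id, format(x$day), nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}

#' Synthesize a six-lead ECG recording
#'
#' Leads I and II are periodic Gaussian-sum beat trains; leads III, aVR, aVL
#' and aVF are derived *before* noise through `III = II - I`,
#' `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`. Per-lead additive
#' Gaussian noise and a low-frequency (<= 0.5 Hz) cosine baseline wander are
#' then added.
#'
#' @param params A [morphology_params()] object.
#' @param duration Record length in seconds.
#' @param fs Sampling rate, 250 or 500 Hz.
#' @param noise_sd SD of additive white noise (mV).
#' @param wander_amp Amplitude of the cosine baseline wander (mV).
#' @param seed Optional integer seed for the noise/wander draws.
#' @param patient_id,day,seq Metadata stored on the recording.
#' @return An [ecg_recording()].
#' @export
synthesize_ecg <- function(params, duration = 10, fs = 250, noise_sd = 0,
                           wander_amp = 0, seed = NULL,
                           patient_id = NA_character_, day = 0, seq = 1L) {
  stopifnot(inherits(params, "morphology_params"), duration > 0)
  if (!fs %in% c(250, 500))
    stop("unsupported sampling rate: ", fs, " (must be 250 or 500 Hz)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 60 / params$heart_rate
  # phase relative to the nearest R peak of the train R_k = period/2 + k*period
  phase <- ((t - period / 2 + period / 2) %% period) - period / 2
  lead_I <- gaussian_lead(phase, params$waves$I, params$t_inversion, period)
  lead_II <- gaussian_lead(phase, params$waves$II, params$t_inversion, period)
  sig <- rbind(I = lead_I,
               II = lead_II,
               III = lead_II - lead_I,
               aVR = -(lead_I + lead_II) / 2,
               aVL = lead_I - lead_II / 2,
               aVF = lead_II - lead_I / 2)
  if (noise_sd > 0 || wander_amp > 0) {
    for (ld in seq_len(nrow(sig))) {
      if (wander_amp > 0) {
        f <- runif(1, 0.05, 0.5)
        phi <- runif(1, 0, 2 * pi)
        sig[ld, ] <- sig[ld, ] + wander_amp * cos(2 * pi * f * t + phi)
      }
      if (noise_sd > 0) sig[ld, ] <- sig[ld, ] + rnorm(n, 0, noise_sd)
    }
  }
  ecg_recording(sig, fs, patient_id = patient_id, day = day, seq = seq)
}

#' True R-peak times of a synthetic recording
#'
#' @param params A [morphology_params()] object.
#' @param duration Record length in seconds.
#' @return Numeric vector of R-peak times (seconds).
#' @export
true_r_times <- function(params, duration = 10) {
  period <- 60 / params$heart_rate
  seq(period / 2, duration, by = period)
}

#' Noiseless mean-beat template directly from morphology parameters
#'
#' Evaluates the Gaussian-sum beat model on the template window grid,
#' including neighbouring-beat spill-over at the current heart rate, derives
#' the augmented leads and (optionally) adds residual template noise before
#' min-max normalisation. This is the closed-form counterpart of averaging
#' R-aligned beats from a synthesized recording.
#'
#' @param params A [morphology_params()] object.
#' @param window Length-2 vector `c(pre, post)` in seconds around the R peak.
#' @param fs Template sampling rate (Hz).
#' @param residual_sd SD (mV) of residual noise added per lead before
#'   normalisation; emulates what survives beat averaging.
#' @param normalize Min-max normalise each lead to `[0, 1]`?
#' @param patient_id,day Metadata.
#' @return A [beat_template()].
#' @export
template_from_params <- function(params, window = c(0.25, 0.45), fs = 250,
                                 residual_sd = 0, normalize = TRUE,
                                 patient_id = NA_character_, day = 0) {
  ws <- window_samples(window, fs)
  tt <- seq(-ws[["pre"]], ws[["post"]] - 1L) / fs
  period <- 60 / params$heart_rate
  lead_I <- gaussian_lead(tt, params$waves$I, params$t_inversion, period)
  lead_II <- gaussian_lead(tt, params$waves$II, params$t_inversion, period)
  sig <- rbind(I = lead_I,
               II = lead_II,
               III = lead_II - lead_I,
               aVR = -(lead_I + lead_II) / 2,
               aVL = lead_I - lead_II / 2,
               aVF = lead_II - lead_I / 2)
  if (residual_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), 0, residual_sd), nrow(sig))
  tpl <- beat_template(sig, fs = fs, window = window, patient_id = patient_id,
                       day = day, normalized = FALSE)
  if (normalize) tpl <- normalize01(tpl) else tpl
}

#' Trajectory configuration for morphology drift and the ECG visit process
#'
#' Drifting parameters (T amplitude in mV, T width in s, heart rate in bpm)
#' follow independent Gaussian random walks on the 90-day grid. ECG visits
#' start with a guaranteed day-0 recording; later inter-visit gaps are
#' normal with the given mean and SD, truncated below.
#'
#' @param step_sd Named vector of per-90-day random-walk step SDs for
#'   `t_amp`, `t_width` and `heart_rate`.
#' @param horizon Administrative censoring horizon in days (48 months).
#' @param interval Grid width in days.
#' @param visit_gap_mean,visit_gap_sd,visit_gap_min Inter-visit gap
#'   distribution (days), truncated at `visit_gap_min`.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(step_sd = c(t_amp = 0.08, t_width = 0.002,
                                          heart_rate = 2),
                              horizon = 1440, interval = 90,
                              visit_gap_mean = 180, visit_gap_sd = 45,
                              visit_gap_min = 30) {
  stopifnot(all(step_sd >= 0), horizon > 0, interval > 0)
  step_sd <- step_sd[c("t_amp", "t_width", "heart_rate")]
  step_sd[is.na(step_sd)] <- 0
  names(step_sd) <- c("t_amp", "t_width", "heart_rate")
  structure(list(step_sd = step_sd, drift_model = "random_walk",
                 horizon = horizon, interval = interval,
                 visit_gap_mean = visit_gap_mean, visit_gap_sd = visit_gap_sd,
                 visit_gap_min = visit_gap_min),
            class = "trajectory_config")
}

#' Random walk of the drifting morphology parameters on the 90-day grid
#'
#' @param params0 Baseline [morphology_params()].
#' @param cfg A [trajectory_config()].
#' @param horizon Horizon in days (defaults to `cfg$horizon`).
#' @param seed Optional integer seed.
#' @return Tibble with one row per grid interval: `k`, `day_start` and the
#'   absolute values of `t_amp` (lead II T amplitude, mV), `t_width` (s) and
#'   `heart_rate` (bpm) in force during that interval.
#' @export
morphology_walk <- function(params0, cfg = trajectory_config(),
                            horizon = cfg$horizon, seed = NULL) {
  stopifnot(horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  K <- ceiling(horizon / cfg$interval)
  sds <- cfg$step_sd
  steps <- cbind(t_amp = c(0, rnorm(K - 1, 0, sds[["t_amp"]])),
                 t_width = c(0, rnorm(K - 1, 0, sds[["t_width"]])),
                 heart_rate = c(0, rnorm(K - 1, 0, sds[["heart_rate"]])))
  walk <- apply(steps, 2, cumsum)
  if (K == 1L) walk <- matrix(walk, nrow = 1, dimnames = list(NULL, colnames(steps)))
  tibble(
    k = 0:(K - 1),
    day_start = (0:(K - 1)) * cfg$interval,
    t_amp = params0$waves$II["T", "amplitude"] + walk[, "t_amp"],
    t_width = pmax(params0$waves$II["T", "width"] + walk[, "t_width"], 0.008),
    heart_rate = pmin(pmax(params0$heart_rate + walk[, "heart_rate"], 30), 180)
  )
}

# morphology at one grid point: lead II T amplitude moves to `t_amp`, lead I
# T amplitude scales proportionally; T width shift applied to both leads
walk_params <- function(params0, t_amp, t_width, heart_rate) {
  p <- params0
  ref <- params0$waves$II["T", "amplitude"]
  ratio <- if (abs(ref) > 1e-12) t_amp / ref else 1
  p$waves$II["T", "amplitude"] <- t_amp
  p$waves$I["T", "amplitude"] <- params0$waves$I["T", "amplitude"] * ratio
  dw <- t_width - params0$waves$II["T", "width"]
  p$waves$II["T", "width"] <- max(params0$waves$II["T", "width"] + dw, 0.008)
  p$waves$I["T", "width"] <- max(params0$waves$I["T", "width"] + dw, 0.008)
  p$heart_rate <- min(max(heart_rate, 30), 180)
  p
}

#' Generate a morphology trajectory sampled at ECG visit days
#'
#' @inheritParams morphology_walk
#' @return Tibble `(day, params)` where `params` is a list-column of
#'   [morphology_params()]; the underlying grid walk is attached as
#'   attribute `"walk"`. A day-0 visit is always present.
#' @export
generate_trajectory <- function(params0, cfg = trajectory_config(),
                                horizon = cfg$horizon, seed = NULL) {
  stopifnot(horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  walk <- morphology_walk(params0, cfg, horizon)
  days <- 0
  repeat {
    gap <- max(rnorm(1, cfg$visit_gap_mean, cfg$visit_gap_sd), cfg$visit_gap_min)
    nxt <- days[length(days)] + round(gap)
    if (nxt > horizon) break
    days <- c(days, nxt)
  }
  ks <- pmin(floor(days / cfg$interval), nrow(walk) - 1) + 1L
  params <- lapply(ks, function(i)
    walk_params(params0, walk$t_amp[i], walk$t_width[i], walk$heart_rate[i]))
  out <- tibble(day = days, params = params)
  attr(out, "walk") <- walk
  attr(out, "params0") <- params0
  out
}

#' Baseline covariate roster configuration
#'
#' Prevalences and moments default to values typical of a large contemporary
#' ICD cohort: 74.5% male, 60.5% primary prevention,
#' LVEF classes 22.8/16.6/60.6%, 41.6% ischaemic cardiomyopathy, 40.6% prior
#' sustained VT/VF, age 61.7 (13.9) years, and typical electrolyte/creatinine
#' moments. Laboratory values receive 10% missingness completely at random;
#' `nt_probnp` is the designated high-missingness column (35%) that
#' exercises the >= 30% exclusion rule downstream.
#'
#' @param ... Overrides for any listed element.
#' @return A named list of class `baseline_config`.
#' @export
baseline_config <- function(...) {
  cfg <- list(
    sex_male = 0.745, primary_prevention = 0.605,
    lvef = c(gt45 = 0.228, mid = 0.166, le35 = 0.606),
    ischaemic = 0.416, prior_vtvf = 0.406, atrial_arrhythmia = 0.308,
    diabetes = 0.196, beta_blocker = 0.766, sotalol = 0.059,
    amiodarone = 0.088,
    age_mean = 61.7, age_sd = 13.9, bmi_mean = 27.1, bmi_sd = 4.2,
    sodium_mean = 139.5, sodium_sd = 2.9,
    potassium_mean = 4.3, potassium_sd = 0.5,
    creatinine_mean = 100.2, creatinine_sd = 60.7,
    lab_missing = 0.10, high_missing_col = "nt_probnp", high_missing = 0.35
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  structure(cfg, class = "baseline_config")
}

#' Generate a baseline covariate table
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed.
#' @param config A [baseline_config()].
#' @return Tibble with one row per patient; lab columns carry injected
#'   missingness, and the configured high-missingness column is missing in
#'   at least 30% of rows.
#' @export
generate_baseline <- function(n_patients, seed = 1L, config = baseline_config()) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive integer", call. = FALSE)
  n <- as.integer(n_patients)
  set.seed(seed)
  cfg <- config
  lvef_p <- cfg$lvef / sum(cfg$lvef)
  miss <- function(x, frac) {
    x[runif(length(x)) < frac] <- NA
    x
  }
  tb <- tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(rnorm(n, cfg$age_mean, cfg$age_sd), 1),
    sex = ifelse(runif(n) < cfg$sex_male, "male", "female"),
    primary_prevention = as.integer(runif(n) < cfg$primary_prevention),
    lvef_class = sample(c("gt45", "mid", "le35"), n, TRUE, prob = lvef_p),
    ischaemic = as.integer(runif(n) < cfg$ischaemic),
    prior_vtvf = as.integer(runif(n) < cfg$prior_vtvf),
    atrial_arrhythmia = as.integer(runif(n) < cfg$atrial_arrhythmia),
    diabetes = as.integer(runif(n) < cfg$diabetes),
    beta_blocker = as.integer(runif(n) < cfg$beta_blocker),
    sotalol = as.integer(runif(n) < cfg$sotalol),
    amiodarone = as.integer(runif(n) < cfg$amiodarone),
    bmi = round(pmax(rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 15), 1),
    sodium = miss(round(rnorm(n, cfg$sodium_mean, cfg$sodium_sd), 1), cfg$lab_missing),
    potassium = miss(round(pmax(rnorm(n, cfg$potassium_mean, cfg$potassium_sd), 2.5), 2),
                     cfg$lab_missing),
    creatinine = miss(round(pmax(rnorm(n, cfg$creatinine_mean, cfg$creatinine_sd), 30), 0),
                      cfg$lab_missing),
    nt_probnp = miss(round(exp(rnorm(n, log(800), 0.8)), 0), cfg$high_missing)
  )
  tb
}

#' Piecewise-constant hazard specification
#'
#' The per-day hazard during 90-day interval k is
#' `lambda = base_hazard * exp(sum_j coef_j * (x_jk - center_j))` where the
#' `x_jk` are the drifting morphology values in force during the interval
#' (`t_amp`, `t_width`, `heart_rate`) and numeric baseline risk covariates
#' (see [baseline_risk_design()]).
#'
#' @param base_hazard Baseline hazard per day (> 0).
#' @param coefs Named log-hazard coefficients for morphology walk columns.
#' @param baseline_coefs Named log-hazard coefficients for baseline design
#'   columns.
#' @param centers Named centering constants for the morphology columns.
#' @return Object of class `hazard_spec`.
#' @export
hazard_spec <- function(base_hazard = 3.5e-5,
                        coefs = c(t_amp = -10),
                        baseline_coefs = c(prior_vtvf = 0.6, lvef_le35 = 0.5),
                        centers = c(t_amp = 0.35)) {
  if (!is.numeric(base_hazard) || base_hazard < 0)
    stop("base_hazard must be a non-negative number", call. = FALSE)
  structure(list(base_hazard = base_hazard, coefs = coefs,
                 baseline_coefs = baseline_coefs, centers = centers),
            class = "hazard_spec")
}

#' Numeric baseline risk design used by the event simulator
#'
#' @param baseline Baseline tibble from [generate_baseline()].
#' @return Tibble of numeric columns (`prior_vtvf`, `lvef_le35`,
#'   `ischaemic`, `primary_prevention`, `sex_male`, `age_std`).
#' @export
baseline_risk_design <- function(baseline) {
  tibble(
    patient_id = baseline$patient_id,
    prior_vtvf = as.numeric(baseline$prior_vtvf),
    lvef_le35 = as.numeric(baseline$lvef_class == "le35"),
    ischaemic = as.numeric(baseline$ischaemic),
    primary_prevention = as.numeric(baseline$primary_prevention),
    sex_male = as.numeric(baseline$sex == "male"),
    age_std = (baseline$age - mean(baseline$age)) / stats::sd(baseline$age)
  )
}

#' Simulate event times from per-interval piecewise-constant hazards
#'
#' For each patient and 90-day interval the event probability is
#' `1 - exp(-lambda * len)` with `lambda` evaluated at that interval's
#' morphology walk values; the event day is uniform within the triggering
#' interval, and patients without events are administratively censored at
#' the horizon.
#'
#' @param walks Tibble of per-patient grid walks: columns `patient_id`, `k`,
#'   `day_start`, `t_amp`, `t_width`, `heart_rate` (stack of
#'   [morphology_walk()] outputs).
#' @param baseline Baseline tibble (for the baseline risk covariates).
#' @param spec A [hazard_spec()].
#' @param horizon Administrative censoring horizon in days.
#' @param seed Optional integer seed.
#' @param interval Interval width in days.
#' @return Outcome tibble `(patient_id, follow_up_days, event, event_day)`.
#' @export
simulate_events <- function(walks, baseline, spec = hazard_spec(),
                            horizon = 1440, seed = NULL, interval = 90) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (spec$base_hazard < 0) stop("non-positive hazard", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- ceiling(horizon / interval)
  bad <- walks |> count(.data$patient_id) |> filter(.data$n < K)
  if (nrow(bad) > 0)
    stop("every patient's trajectory must cover the horizon", call. = FALSE)
  design <- baseline_risk_design(baseline)
  bterm <- rep(0, nrow(design))
  for (nm in names(spec$baseline_coefs)) {
    if (!nm %in% names(design))
      stop("unknown baseline covariate in hazard spec: ", nm, call. = FALSE)
    bterm <- bterm + spec$baseline_coefs[[nm]] * design[[nm]]
  }
  names(bterm) <- design$patient_id

  w <- walks |> arrange(.data$patient_id, .data$k)
  mterm <- rep(0, nrow(w))
  for (nm in names(spec$coefs)) {
    ctr <- if (nm %in% names(spec$centers)) spec$centers[[nm]] else 0
    mterm <- mterm + spec$coefs[[nm]] * (w[[nm]] - ctr)
  }
  w$lambda <- spec$base_hazard * exp(mterm + bterm[w$patient_id])

  w <- w |> filter(.data$k < K)
  len <- pmin(interval, horizon - w$day_start)
  hit <- runif(nrow(w)) < 1 - exp(-w$lambda * len)
  u_day <- ceiling(runif(nrow(w)) * len)      # event day within interval
  first_hit <- suppressWarnings(
    tapply(ifelse(hit, w$k, NA_real_), w$patient_id, min, na.rm = TRUE))
  first_hit[!is.finite(first_hit)] <- NA_real_
  pats <- names(first_hit)
  key <- paste(w$patient_id, w$k)
  ev_day <- w$day_start[match(paste(pats, first_hit), key)] +
    u_day[match(paste(pats, first_hit), key)]
  tibble(patient_id = pats,
         follow_up_days = as.numeric(ifelse(is.na(first_hit), horizon, ev_day)),
         event = as.integer(!is.na(first_hit)),
         event_day = as.numeric(ifelse(is.na(first_hit), NA_real_, ev_day)))
}

#' Simulate a complete synthetic ICD cohort
#'
#' Draws baseline covariates, per-patient beat morphologies, morphology
#' random walks, irregular ECG visit schedules and event/censoring times,
#' then truncates each patient's visits at their follow-up end. Every
#' patient retains the guaranteed day-0 visit.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `seed` and the configuration objects.
#' @param baseline_cfg A [baseline_config()].
#' @param traj_cfg A [trajectory_config()].
#' @param spec A [hazard_spec()].
#' @param morph_args List of overrides passed to [random_morphology()].
#' @return Object of class `synthetic_cohort`: list with tibbles `baseline`,
#'   `outcomes`, `visits` (`patient_id`, `day`, `params` list-column),
#'   `walks`, plus the configuration and seed.
#' @export
simulate_cohort <- function(n_patients, seed = 1L,
                            baseline_cfg = baseline_config(),
                            traj_cfg = trajectory_config(),
                            spec = hazard_spec(),
                            morph_args = list()) {
  stopifnot(n_patients >= 1)
  baseline <- generate_baseline(n_patients, seed = seed, config = baseline_cfg)
  morphs <- do.call(random_morphology,
                    c(list(n = n_patients, seed = seed + 1000L), morph_args))
  set.seed(seed + 2000L)
  walks <- vector("list", n_patients)
  visits <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    traj <- generate_trajectory(morphs[[i]], traj_cfg)
    wk <- attr(traj, "walk")
    wk$patient_id <- baseline$patient_id[i]
    walks[[i]] <- wk
    traj$patient_id <- baseline$patient_id[i]
    visits[[i]] <- traj
  }
  walks <- bind_rows(walks)
  visits <- bind_rows(visits)
  outcomes <- simulate_events(walks, baseline, spec,
                              horizon = traj_cfg$horizon,
                              seed = seed + 3000L,
                              interval = traj_cfg$interval)
  fup <- setNames(outcomes$follow_up_days, outcomes$patient_id)
  visits <- visits |> filter(.data$day <= fup[.data$patient_id])
  structure(list(baseline = baseline, outcomes = outcomes,
                 visits = visits[, c("patient_id", "day", "params")],
                 walks = walks,
                 morphologies = setNames(morphs, baseline$patient_id),
                 config = list(baseline = baseline_cfg, trajectory = traj_cfg,
                               hazard = spec),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d ECG visits, %d events (seed %d)\n",
              nrow(x$baseline), nrow(x$visits), sum(x$outcomes$event), x$seed))
  invisible(x)
}

#' Raw ECG recordings for every visit of a synthetic cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param duration,fs,noise_sd,wander_amp Passed to [synthesize_ecg()].
#' @param seed Integer seed for the noise draws.
#' @return List of [ecg_recording()] objects, one per visit.
#' @export
cohort_recordings <- function(cohort, duration = 10, fs = 250,
                              noise_sd = 0.03, wander_amp = 0.10, seed = 1L) {
  set.seed(seed)
  purrr::pmap(cohort$visits, function(patient_id, day, params) {
    synthesize_ecg(params, duration = duration, fs = fs, noise_sd = noise_sd,
                   wander_amp = wander_amp, patient_id = patient_id, day = day)
  })
}

#' Beat templates for every visit of a synthetic cohort
#'
#' `method = "analytic"` evaluates the closed-form beat model on the template
#' window (fast; used for large simulation studies); `method = "preprocess"`
#' synthesizes a full noisy recording per visit and runs the complete
#' filtering / R-peak / averaging pipeline (slow; exercises the whole path).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param method `"analytic"` or `"preprocess"`.
#' @param residual_sd Analytic-path residual template noise (mV).
#' @param noise_sd,wander_amp Preprocess-path raw-signal noise settings.
#' @param window Template window `c(pre, post)` seconds.
#' @param seed Integer seed.
#' @return Template table: tibble `(patient_id, day, template)` where
#'   `template` is a list-column of [beat_template()] objects.
#' @export
cohort_templates <- function(cohort, method = c("analytic", "preprocess"),
                             residual_sd = 0.01, noise_sd = 0.03,
                             wander_amp = 0.10, window = c(0.25, 0.45),
                             seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  tpls <- purrr::pmap(cohort$visits, function(patient_id, day, params) {
    if (method == "analytic") {
      template_from_params(params, window = window, residual_sd = residual_sd,
                           patient_id = patient_id, day = day)
    } else {
      rec <- synthesize_ecg(params, noise_sd = noise_sd,
                            wander_amp = wander_amp,
                            patient_id = patient_id, day = day)
      preprocess_recording(rec, window = window)
    }
  })
  tibble(patient_id = cohort$visits$patient_id, day = cohort$visits$day,
         template = tpls)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `baseline.csv`, `outcomes.csv`, a long-format ECG visit parameter
#' table and a JSON manifest recording the seed and configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$walks, file.path(dir, "morphology_walks.csv"),
                   row.names = FALSE)
  visits <- cohort$visits |>
    mutate(heart_rate = purrr::map_dbl(.data$params, "heart_rate"),
           t_amp = purrr::map_dbl(.data$params,
                                  ~ .x$waves$II["T", "amplitude"])) |>
    select("patient_id", "day", "heart_rate", "t_amp")
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)
  manifest <- list(seed = cohort$seed,
                   n_patients = nrow(cohort$baseline),
                   n_visits = nrow(cohort$visits),
                   horizon = cohort$config$trajectory$horizon)
  path <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
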