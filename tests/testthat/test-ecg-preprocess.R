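test_that("resampling passes 250 Hz through and halves 500 Hz correctly", {
  p <- morphology_params()
  r250 <- synthesize_ecg(p, noise_sd = 0, wander_amp = 0)
  expect_identical(resample_to_250(r250), r250)

  r500 <- synthesize_ecg(p, fs = 500, noise_sd = 0, wander_amp = 0)
  out <- resample_to_250(r500)
  expect_equal(out$fs, 250)
  expect_equal(ncol(out$signal), 2500)

  # pure 10 Hz sine survives decimation with amplitude preserved within 1%
  t5 <- (0:4999) / 500
  sine <- rbind(II = sin(2 * pi * 10 * t5))
  rec <- ecg_recording(sine, 500)
  dec <- resample_to_250(rec)$signal[1, ]
  spec_in <- Mod(stats::fft(sine[1, ]))[1:2500]
  spec_out <- Mod(stats::fft(dec))[1:1250]
  f_in <- (which.max(spec_in[-1])) * 500 / 5000
  f_out <- (which.max(spec_out[-1])) * 250 / 2500
  expect_equal(f_in, 10)
  expect_equal(f_out, 10)
  interior <- dec[100:2400]
  expect_lt(abs(max(interior) - 1), 0.01)

  expect_error(resample_to_250(ecg_recording(sine, 250) |>
                                 (\(r) { r$fs <- 100; r })()),
               "unsupported")
})

test_that("Savitzky-Golay smoothing reproduces cubics, shrinks noise, keeps constants", {
  x <- seq(-1, 1, length.out = 400)
  cubic <- 2 + x - 0.5 * x^2 + 0.3 * x^3
  sm <- denoise(cubic, window = 15, order = 3)
  interior <- 20:380
  expect_lt(max(abs(sm[interior] - cubic[interior])), 1e-10)

  set.seed(1)
  noise <- rnorm(2000)
  expect_lt(var(denoise(noise)), var(noise))

  const <- rep(0.7, 100)
  expect_equal(denoise(const), const, tolerance = 1e-12)
  expect_error(denoise(const, window = 101), "window")
})

test_that("cosine-series baseline removal cancels in-band wander", {
  fs <- 250
  t <- (0:2499) / fs
  wander <- 0.4 * cos(2 * pi * 0.3 * t)   # on the cosine basis grid
  res <- remove_baseline_wander(wander, fs)
  expect_lt(max(abs(res)), 0.05 * 0.4)

  expect_equal(remove_baseline_wander(rep(0, 2500), fs), rep(0, 2500),
               tolerance = 1e-12)

  # removing injected wander moves a beat train back toward the clean signal
  p <- morphology_params()
  clean <- synthesize_ecg(p, noise_sd = 0, wander_amp = 0)$signal["II", ]
  dirty <- clean + 0.3 * cos(2 * pi * 0.3 * t + 0.8)
  cleaned <- remove_baseline_wander(dirty, fs)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(cleaned, clean - mean(clean)), rmse(dirty, clean))

  expect_error(remove_baseline_wander(rep(0, 100), fs), "one second")
})

test_that("R-peak detection is accurate on clean and noisy records", {
  p <- morphology_params(heart_rate = 60)
  rec <- synthesize_ecg(p, duration = 10, noise_sd = 0, wander_amp = 0)
  peaks <- detect_r_peaks(rec$signal["II", ], 250)
  expect_gte(length(peaks), 9)
  expect_lte(length(peaks), 11)
  truth <- true_r_times(p, 10) * 250
  err <- vapply(peaks, function(pk) min(abs(pk - truth)), numeric(1))
  expect_true(all(err <= 0.04 * 250))

  # noise at 10% of R amplitude: recall and precision at +/-40 ms
  hits <- 0; n_true <- 0; n_det <- 0
  for (s in 1:20) {
    q <- random_morphology(1, seed = s)[[1]]
    rn <- synthesize_ecg(q, noise_sd = 0.1 * q$waves$II["R", "amplitude"],
                         wander_amp = 0.1, seed = s)
    filt <- denoise(rn$signal["II", ])
    filt <- remove_baseline_wander(filt, 250)
    pk <- detect_r_peaks(filt, 250)
    tr <- true_r_times(q, 10) * 250
    tr <- tr[tr > 10 & tr < 2490]
    n_true <- n_true + length(tr); n_det <- n_det + length(pk)
    hits <- hits + sum(vapply(tr, function(x) any(abs(pk - x) <= 10), logical(1)))
  }
  expect_gte(hits / n_true, 0.99)
  expect_gte(hits / n_det, 0.99)

  expect_equal(detect_r_peaks(rep(0, 1000), 250), integer(0))
  expect_error(detect_r_peaks(rep(0, 100), 250), "two seconds")
})

test_that("beat averaging obeys the mean and sqrt(N) noise laws", {
  p <- morphology_params(heart_rate = 60)
  rec <- synthesize_ecg(p, duration = 10, noise_sd = 0, wander_amp = 0)
  peaks <- round(true_r_times(p, 10) * 250)
  tpl <- extract_mean_template(rec, peaks)
  # identical repeated beats: template equals any single beat window
  one <- rec$signal[, (peaks[5] - 62):(peaks[5] + 112)]
  expect_equal(tpl$waveforms, one, tolerance = 1e-8,
               ignore_attr = TRUE)

  # i.i.d. noise shrinks as 1/sqrt(N) across beats
  sigma <- 0.05
  resids <- vapply(1:30, function(s) {
    noisy <- rec
    set.seed(s)
    noisy$signal <- rec$signal + matrix(rnorm(length(rec$signal), 0, sigma),
                                        nrow(rec$signal))
    tn <- extract_mean_template(noisy, peaks)
    sd(tn$waveforms - tpl$waveforms)
  }, numeric(1))
  expect_lt(abs(mean(resids) / (sigma / sqrt(length(peaks))) - 1), 0.25)

  expect_error(extract_mean_template(rec, peaks[1:2]), "insufficient beats")
})

test_that("min-max normalisation is exact, idempotent and handles constants", {
  w <- rbind(II = seq(-1, 1, length.out = 175))
  tpl <- beat_template(w)
  n1 <- normalize01(tpl)
  expect_equal(range(n1$waveforms), c(0, 1))
  expect_equal(normalize01(n1)$waveforms, n1$waveforms, tolerance = 1e-12)

  const <- beat_template(rbind(II = rep(3, 175)))
  expect_true(all(normalize01(const)$waveforms == 0.5))
})

test_that("same-day deduplication keeps the first recording and preserves chronology", {
  p <- morphology_params()
  mk <- function(day, seq) synthesize_ecg(p, duration = 3, patient_id = "A",
                                          day = day, seq = seq)
  recs <- list(mk(40, 1), mk(40, 2), mk(40, 3), mk(10, 1), mk(80, 1))
  out <- dedupe_same_day(recs)
  expect_equal(length(out), 3)
  days <- vapply(out, function(r) r$day, numeric(1))
  expect_equal(days, c(10, 40, 80))
  kept40 <- out[[which(days == 40)]]
  expect_equal(kept40$seq, 1L)

  distinct <- list(mk(1, 1), mk(2, 1))
  expect_equal(length(dedupe_same_day(distinct)), 2)
  expect_equal(length(dedupe_same_day(list())), 0)
})

test_that("full preprocessing is stable when reapplied (idempotence)", {
  p <- morphology_params()
  rec <- synthesize_ecg(p, noise_sd = 0.03, wander_amp = 0.1, seed = 6)
  once <- t(apply(rec$signal, 1, function(x)
    remove_baseline_wander(denoise(x), 250)))
  twice <- t(apply(once, 1, function(x)
    remove_baseline_wander(denoise(x), 250)))
  rel <- sqrt(mean((twice - once)^2)) / diff(range(once))
  expect_lt(rel, 0.01)

  # template contract: same length and lead order for every recording
  tpl1 <- preprocess_recording(rec)
  tpl2 <- preprocess_recording(synthesize_ecg(random_morphology(1, seed = 8)[[1]],
                                              noise_sd = 0.03, wander_amp = 0.1,
                                              seed = 9))
  expect_identical(dim(tpl1$waveforms), dim(tpl2$waveforms))
  expect_identical(tpl1$leads, tpl2$leads)
  expect_true(all(tpl1$waveforms >= 0 & tpl1$waveforms <= 1))
})
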