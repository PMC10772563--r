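# one shared definition of the template grid: L = round(total * fs) samples,
# `pre` of them strictly before the R peak
window_samples <- function(window, fs) {
  L <- round(sum(window) * fs)
  pre <- floor(window[1] * fs)
  c(pre = pre, post = L - pre)
}

#' Construct a beat-template object
#'
#' A beat template is the per-lead mean heartbeat waveform of one recording,
#' stored as a leads x samples matrix on a fixed window around the R peak.
#'
#' @param waveforms Numeric leads x samples matrix with lead row names.
#' @param fs Sampling rate (Hz) of the template grid.
#' @param window Length-2 vector `c(pre, post)` in seconds around R.
#' @param patient_id,day Metadata.
#' @param normalized Logical: has per-lead min-max normalisation been applied?
#' @return Object of class `beat_template`.
#' @export
beat_template <- function(waveforms, fs = 250, window = c(0.25, 0.45),
                          patient_id = NA_character_, day = 0,
                          normalized = FALSE) {
  stopifnot(is.matrix(waveforms), !is.null(rownames(waveforms)))
  structure(list(patient_id = patient_id, day = day, fs = fs,
                 window = window, leads = rownames(waveforms),
                 waveforms = waveforms, normalized = normalized),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> patient %s, day %s: %d leads x %d samples%s\n",
              x$patient_id, format(x$day), nrow(x$waveforms),
              ncol(x$waveforms), if (x$normalized) " (normalised)" else ""))
  invisible(x)
}

#' Flatten a beat template into the concatenated-lead feature vector
#'
#' Leads are concatenated in their stored order; this fixed layout is the
#' VAE input contract.
#'
#' @param tpl A [beat_template()].
#' @return Numeric vector of length `n_leads * L`.
#' @export
template_vector <- function(tpl) {
  as.vector(t(tpl$waveforms))
}

#' Stack a template table into a samples-by-features matrix
#'
#' @param templates Tibble with a `template` list-column (from
#'   [cohort_templates()] or [preprocess_cohort()]).
#' @return Numeric matrix, one row per template; lead layout stored in
#'   attributes `leads` and `L`.
#' @export
template_matrix <- function(templates) {
  stopifnot("template" %in% names(templates))
  first <- templates$template[[1]]
  X <- t(vapply(templates$template, template_vector,
                numeric(nrow(first$waveforms) * ncol(first$waveforms))))
  attr(X, "leads") <- first$leads
  attr(X, "L") <- ncol(first$waveforms)
  attr(X, "fs") <- first$fs
  attr(X, "window") <- first$window
  X
}

#' Downsample a recording to 250 Hz
#'
#' 500 Hz records are factor-2 decimated after an anti-alias low-pass
#' (FIR, via [signal::decimate()]); 250 Hz records pass through unchanged.
#'
#' @param rec An [ecg_recording()].
#' @return An [ecg_recording()] at 250 Hz.
#' @export
resample_to_250 <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (rec$fs == 250) return(rec)
  if (rec$fs != 500)
    stop("unsupported sampling rate: ", rec$fs, call. = FALSE)
  sig <- t(apply(rec$signal, 1, function(x)
    signal::decimate(x, q = 2, ftype = "fir")))
  rownames(sig) <- rownames(rec$signal)
  ecg_recording(sig, 250, patient_id = rec$patient_id, day = rec$day,
                seq = rec$seq)
}

#' Savitzky-Golay smoothing of a single-lead waveform
#'
#' @param x Numeric waveform.
#' @param window Odd filter window length in samples (60 ms at 250 Hz by
#'   default).
#' @param order Polynomial order.
#' @return Smoothed waveform of the same length.
#' @export
denoise <- function(x, window = 15, order = 3) {
  if (window >= length(x))
    stop("filter window must be shorter than the signal", call. = FALSE)
  signal::sgolayfilt(x, p = order, n = window)
}

#' Remove baseline wander by subtracting a low-resolution cosine series
#'
#' Fits, by least squares, an intercept plus cosine terms at frequencies
#' `k / (2 * duration)` for `k = 1..K`, with `K` chosen so the maximum
#' frequency does not exceed `max_freq`, and returns the residual.
#'
#' @param x Numeric waveform (>= 1 s of signal).
#' @param fs Sampling rate (Hz).
#' @param max_freq Highest cosine frequency retained (Hz).
#' @return Waveform with the fitted drift removed.
#' @export
remove_baseline_wander <- function(x, fs, max_freq = 0.7) {
  n <- length(x)
  if (n < fs) stop("need at least one second of signal", call. = FALSE)
  duration <- n / fs
  K <- floor(max_freq * 2 * duration)
  if (K < 1) return(x - mean(x))
  t <- (seq_len(n) - 1) / fs
  B <- vapply(seq_len(K), function(k) cos(pi * k * t / duration), numeric(n))
  fit <- stats::lm.fit(cbind(1, B), x)
  x - fit$fitted.values
}

#' Detect R peaks on a lead-II waveform
#'
#' Band-passes the signal (5-20 Hz Butterworth, zero-phase), squares its
#' first difference, smooths the energy, thresholds, and picks one peak per
#' supra-threshold run with a 0.24 s refractory period. Each detection is
#' refined to the local signal maximum within +/- 60 ms.
#'
#' @param x Numeric lead-II waveform (>= 2 s).
#' @param fs Sampling rate (Hz).
#' @param refractory Minimum inter-peak distance (s).
#' @return Strictly increasing integer sample indices (possibly empty).
#' @export
detect_r_peaks <- function(x, fs, refractory = 0.24) {
  n <- length(x)
  if (n < 2 * fs) stop("need at least two seconds of signal", call. = FALSE)
  if (all(abs(x - x[1]) < 1e-12)) return(integer(0))
  bp <- signal::filtfilt(signal::butter(3, c(5, 20) / (fs / 2), "pass"), x)
  e <- c(0, diff(bp))^2
  w <- max(3L, round(0.12 * fs))
  s <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- 0
  thr <- 0.4 * quantile(s, 0.99, names = FALSE)
  if (thr <= 0) return(integer(0))
  above <- s > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(s[seg])])
  }
  if (length(cand) == 0) return(integer(0))
  # refractory enforcement on the energy peaks, strongest-first
  keep <- logical(length(cand))
  ord <- order(s[cand], decreasing = TRUE)
  taken <- integer(0)
  min_gap <- round(refractory * fs)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])
  # refine each detection to the local maximum of the input waveform
  half <- round(0.06 * fs)
  peaks <- vapply(cand, function(ix) {
    lo <- max(1L, ix - half); hi <- min(n, ix + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # a second refractory pass after refinement
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) if (p - out[length(out)] >= min_gap) out <- c(out, p)
    peaks <- out
  }
  peaks
}

#' Average R-aligned beats into a mean-beat template
#'
#' @param rec An [ecg_recording()] (250 Hz).
#' @param r_peaks Integer R-peak sample indices.
#' @param window Length-2 `c(pre, post)` in seconds around the R peak.
#' @return An unnormalised [beat_template()].
#' @export
extract_mean_template <- function(rec, r_peaks, window = c(0.25, 0.45)) {
  stopifnot(inherits(rec, "ecg_recording"))
  fs <- rec$fs
  ws <- window_samples(window, fs)
  pre <- ws[1]; post <- ws[2]
  n <- ncol(rec$signal)
  usable <- r_peaks[r_peaks - pre >= 1 & r_peaks + post - 1 <= n]
  if (length(usable) < 3)
    stop("insufficient beats: need >= 3 beats with a full window, got ",
         length(usable), call. = FALSE)
  L <- pre + post
  tplm <- matrix(0, nrow(rec$signal), L, dimnames = list(rec$leads, NULL))
  for (r in usable)
    tplm <- tplm + rec$signal[, (r - pre):(r + post - 1), drop = FALSE]
  tplm <- tplm / length(usable)
  beat_template(tplm, fs = fs, window = window, patient_id = rec$patient_id,
                day = rec$day, normalized = FALSE)
}

#' Min-max normalise a beat template to \[0, 1\] per lead
#'
#' Constant leads map to the all-0.5 waveform by convention.
#'
#' @param tpl A [beat_template()].
#' @return Normalised [beat_template()]; idempotent.
#' @export
normalize01 <- function(tpl) {
  stopifnot(inherits(tpl, "beat_template"))
  w <- tpl$waveforms
  for (i in seq_len(nrow(w))) {
    rng <- range(w[i, ])
    if (diff(rng) < 1e-12) w[i, ] <- 0.5
    else w[i, ] <- (w[i, ] - rng[1]) / diff(rng)
  }
  tpl$waveforms <- w
  tpl$normalized <- TRUE
  tpl
}

#' Keep only the first ECG per patient per day
#'
#' Recordings carry a within-day order (`seq`); for each `(patient, day)` the
#' earliest is kept. Output is ordered by patient and strictly increasing
#' day, never reordering within a patient's chronology.
#'
#' @param recordings List of [ecg_recording()] objects.
#' @return Filtered list.
#' @export
dedupe_same_day <- function(recordings) {
  if (length(recordings) == 0) return(recordings)
  meta <- tibble(
    idx = seq_along(recordings),
    patient_id = purrr::map_chr(recordings, ~ as.character(.x$patient_id)),
    day = purrr::map_dbl(recordings, "day"),
    seq = purrr::map_dbl(recordings, ~ as.numeric(.x$seq %||% 1))
  )
  keep <- meta |>
    arrange(.data$patient_id, .data$day, .data$seq, .data$idx) |>
    group_by(.data$patient_id, .data$day) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$patient_id, .data$day)
  recordings[keep$idx]
}

#' Full preprocessing of one recording into a normalised template
#'
#' Resamples to 250 Hz, Savitzky-Golay filters and removes baseline wander
#' per lead, detects R peaks on lead II, averages beats and min-max
#' normalises.
#'
#' @param rec An [ecg_recording()].
#' @param window Beat window `c(pre, post)` in seconds.
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param wander_max_freq Cosine-series cutoff (Hz).
#' @return A normalised [beat_template()].
#' @export
preprocess_recording <- function(rec, window = c(0.25, 0.45), sg_window = 15,
                                 sg_order = 3, wander_max_freq = 0.7) {
  rec <- resample_to_250(rec)
  sig <- rec$signal
  for (i in seq_len(nrow(sig))) {
    sig[i, ] <- denoise(sig[i, ], window = sg_window, order = sg_order)
    sig[i, ] <- remove_baseline_wander(sig[i, ], rec$fs, wander_max_freq)
  }
  clean <- ecg_recording(sig, rec$fs, patient_id = rec$patient_id,
                         day = rec$day, seq = rec$seq)
  ii <- if ("II" %in% clean$leads) "II" else clean$leads[1]
  peaks <- detect_r_peaks(clean$signal[ii, ], clean$fs)
  tpl <- extract_mean_template(clean, peaks, window = window)
  normalize01(tpl)
}

#' Preprocess a list of recordings into a template table
#'
#' Applies same-day deduplication then [preprocess_recording()] to each
#' remaining recording. Recordings whose template extraction fails (too few
#' usable beats) are dropped with a warning.
#'
#' @param recordings List of [ecg_recording()] objects.
#' @param ... Passed to [preprocess_recording()].
#' @return Tibble `(patient_id, day, template)`.
#' @export
preprocess_cohort <- function(recordings, ...) {
  recordings <- dedupe_same_day(recordings)
  res <- purrr::map(recordings, function(r)
    tryCatch(preprocess_recording(r, ...), error = function(e) NULL))
  failed <- vapply(res, is.null, logical(1))
  if (any(failed))
    warning(sum(failed), " recording(s) dropped (insufficient usable beats)",
            call. = FALSE)
  res <- res[!failed]
  tibble(patient_id = purrr::map_chr(res, ~ as.character(.x$patient_id)),
         day = purrr::map_dbl(res, "day"),
         template = res)
}
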