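#' Empirical percentiles of each latent dimension over a cohort
#'
#' @param codes Latent code tibble (`AE*` columns) or numeric matrix with at
#'   least 20 rows.
#' @param probs Percentile grid (5th, 25th, 75th, 95th).
#' @return Tibble `(dimension, percentile, value)`; linear-interpolation
#'   (type 7) quantiles.
#' @export
latent_percentiles <- function(codes, probs = c(0.05, 0.25, 0.75, 0.95)) {
  M <- if (is.data.frame(codes))
    as.matrix(codes[, grep("^AE", names(codes), value = TRUE), drop = FALSE])
  else as.matrix(codes)
  if (nrow(M) < 20)
    stop("need at least 20 latent codes to estimate percentiles",
         call. = FALSE)
  purrr::map_dfr(colnames(M) %||% paste0("AE", seq_len(ncol(M)) - 1L),
                 function(nm) {
    j <- match(nm, colnames(M) %||% nm)
    q <- quantile(M[, j], probs = probs, type = 7, names = FALSE)
    tibble(dimension = nm, percentile = 100 * probs, value = q)
  })
}

#' Latent factor traversal
#'
#' Sets latent dimension `j` of a reference vector to each grid value (the
#' cohort percentiles of that dimension), decodes every altered vector, and
#' records the per-sample absolute difference to the decoded reference — the
#' traversal heatmap showing which part of the waveform the dimension
#' controls.
#'
#' @param model A trained `ecg_vae`.
#' @param j Latent dimension, 1-based index or `"AE<k>"` name.
#' @param values Grid values for dimension `j` (e.g. its cohort 5/25/75/95th
#'   percentiles).
#' @param reference Reference latent vector (length 16); typically the
#'   element-wise median of the training cohort's posterior means.
#' @param leads,L Lead labout of the template vector (for plotting);
#'   defaults taken from the model input if divisible by 6.
#' @return Object of class `latent_traversal`: reference reconstruction,
#'   per-grid reconstructions and the non-negative difference heatmap
#'   (grid x samples).
#' @export
traverse_latent <- function(model, j, values, reference,
                            leads = NULL, L = NULL) {
  stopifnot(inherits(model, "ecg_vae"), length(reference) == model$latent_dim)
  if (is.character(j)) j <- as.integer(sub("^AE", "", j)) + 1L
  if (is.na(j) || j < 1 || j > model$latent_dim)
    stop("latent index out of range", call. = FALSE)
  # decode the reference inside the same matrix call so that a grid value
  # equal to the reference reproduces it bitwise
  Z <- matrix(rep(reference, each = length(values) + 1L),
              nrow = length(values) + 1L)
  Z[-1, j] <- values
  dec <- decode(model, Z)
  ref_hat <- dec[1, ]
  recons <- dec[-1, , drop = FALSE]
  heat <- abs(sweep(recons, 2, ref_hat))
  if (is.null(leads) && model$input_dim %% 6 == 0) {
    leads <- LIMB_LEADS
    L <- model$input_dim / 6
  }
  structure(list(j = j, dimension = paste0("AE", j - 1L),
                 reference = reference, values = values,
                 reference_recon = ref_hat, recons = recons, heatmap = heat,
                 leads = leads, L = L),
            class = "latent_traversal")
}

#' @export
print.latent_traversal <- function(x, ...) {
  cat(sprintf("<latent_traversal> %s over %d grid values, template length %d\n",
              x$dimension, length(x$values), length(x$reference_recon)))
  invisible(x)
}

#' @export
tidy.latent_traversal <- function(x, ...) {
  grid <- tibble(grid = rep(seq_along(x$values), each = ncol(x$recons)),
                 value = rep(x$values, each = ncol(x$recons)),
                 sample = rep(seq_len(ncol(x$recons)), length(x$values)),
                 recon = as.vector(t(x$recons)),
                 abs_diff = as.vector(t(x$heatmap)))
  if (!is.null(x$leads)) {
    grid$lead <- x$leads[ceiling(grid$sample / x$L)]
    grid$lead_sample <- (grid$sample - 1L) %% x$L + 1L
  }
  grid
}

#' Mean absolute traversal difference within a lead/time window
#'
#' Utility for quantifying which ECG segment a latent dimension perturbs:
#' averages the traversal heatmap over the samples of `lead` falling in
#' `window` seconds relative to the R peak.
#'
#' @param trav A [traverse_latent()] result.
#' @param lead Lead label.
#' @param window `c(from, to)` seconds relative to the R peak.
#' @param template_window The template's `c(pre, post)` window (s).
#' @param fs Template sampling rate.
#' @return Scalar mean absolute difference.
#' @export
traversal_window_effect <- function(trav, lead, window,
                                    template_window = c(0.25, 0.45),
                                    fs = 250) {
  stopifnot(!is.null(trav$leads))
  li <- match(lead, trav$leads)
  ws <- window_samples(template_window, fs)
  t_rel <- seq(-ws[["pre"]], ws[["post"]] - 1L) / fs
  sel <- which(t_rel >= window[1] & t_rel <= window[2]) + (li - 1L) * trav$L
  mean(trav$heatmap[, sel])
}

#' Correlate latent dimensions with interpretable features
#'
#' Pearson correlation of every latent column against every feature column,
#' on aligned rows. Zero-variance columns produce `NA` entries.
#'
#' @param codes Tibble with `AE*` columns (and optionally `patient_id`,
#'   `day`).
#' @param features Tibble of interpretable measurements, same row order (or
#'   joined on `patient_id` + `day` when both carry them).
#' @return Correlation matrix (latents x features) with attribute `n`.
#' @export
correlate_latents <- function(codes, features) {
  join_keys <- intersect(intersect(c("patient_id", "day"), names(codes)),
                         names(features))
  if (length(join_keys) > 0) {
    merged <- inner_join(codes, features, by = join_keys)
  } else {
    if (nrow(codes) != nrow(features))
      stop("rows are not aligned and no join keys are present", call. = FALSE)
    merged <- bind_cols(codes, features)
  }
  lat_cols <- grep("^AE", names(codes), value = TRUE)
  feat_cols <- setdiff(names(features), join_keys)
  M <- matrix(NA_real_, length(lat_cols), length(feat_cols),
              dimnames = list(lat_cols, feat_cols))
  for (a in lat_cols) for (b in feat_cols) {
    x <- merged[[a]]; y <- merged[[b]]
    if (stats::sd(x) > 1e-12 && stats::sd(y) > 1e-12)
      M[a, b] <- cor(x, y)
  }
  attr(M, "n") <- nrow(merged)
  M
}

#' Simple interpretable measurements from beat templates
#'
#' Heart-rate proxy and QRS width estimated directly from the normalised
#' lead-II template: QRS width is the span of samples exceeding half the
#' R-peak prominence around the template R position.
#'
#' @param templates Template table `(patient_id, day, template)`.
#' @return Tibble `(patient_id, day, qrs_width_ms, r_amplitude)`.
#' @export
template_measurements <- function(templates) {
  purrr::pmap_dfr(templates, function(patient_id, day, template) {
    w <- template$waveforms["II", ]
    fs <- template$fs
    pre <- round(template$window[1] * fs)
    r_ix <- pre + 1L
    half <- (w[r_ix] + min(w)) / 2
    above <- w > half
    lo <- r_ix; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- r_ix; while (hi < length(w) && above[hi + 1]) hi <- hi + 1
    tibble(patient_id = patient_id, day = day,
           qrs_width_ms = 1000 * (hi - lo + 1) / fs,
           r_amplitude = w[r_ix])
  })
}
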