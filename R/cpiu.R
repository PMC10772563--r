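#' Impute, one-hot encode and standardise a baseline table
#'
#' Columns with >= `miss_threshold` missingness (measured on the training
#' fold) are dropped; remaining missing values are filled by iterative
#' random-forest imputation (models fit on training-fold rows only, then
#' applied everywhere); categoricals are one-hot encoded and continuous
#' columns z-scored with training-fold statistics.
#'
#' @param baseline Baseline tibble containing `patient_id`.
#' @param train_ids Patient ids forming the training fold; defaults to all
#'   patients.
#' @param miss_threshold Missingness fraction at or above which a column is
#'   excluded (0.3).
#' @param max_iter Imputation sweeps.
#' @param seed Integer seed for the random forests.
#' @return Tibble `patient_id` + numeric features; attributes
#'   `dropped_columns`, `centers`, `scales` and `provenance` (the training
#'   ids the statistics derive from).
#' @export
impute_and_encode <- function(baseline, train_ids = NULL, miss_threshold = 0.3,
                              max_iter = 3, seed = 1L) {
  stopifnot("patient_id" %in% names(baseline))
  ids <- baseline$patient_id
  train_ids <- train_ids %||% ids
  tr <- ids %in% train_ids
  if (!any(tr)) stop("no training rows", call. = FALSE)
  dat <- baseline[, setdiff(names(baseline), "patient_id")]

  miss_frac <- vapply(dat[tr, ], function(x) mean(is.na(x)), numeric(1))
  dropped <- names(miss_frac)[miss_frac >= miss_threshold]
  dat <- dat[, setdiff(names(dat), dropped), drop = FALSE]
  all_na <- vapply(dat[tr, ], function(x) all(is.na(x)), logical(1))
  if (any(all_na))
    stop("column(s) entirely missing in the training fold: ",
         paste(names(dat)[all_na], collapse = ", "), call. = FALSE)

  chr <- vapply(dat, function(x) is.character(x) || is.factor(x), logical(1))
  for (nm in names(dat)[chr]) dat[[nm]] <- factor(dat[[nm]])

  # initial fill with training mean / mode, then iterative RF refinement
  na_idx <- lapply(dat, function(x) which(is.na(x)))
  for (nm in names(dat)) {
    x <- dat[[nm]]
    if (!length(na_idx[[nm]])) next
    fill <- if (is.factor(x)) {
      tb <- table(x[tr])
      factor(names(tb)[which.max(tb)], levels = levels(x))
    } else mean(x[tr], na.rm = TRUE)
    dat[[nm]][na_idx[[nm]]] <- fill
  }
  set.seed(seed)
  to_impute <- names(dat)[vapply(na_idx, length, integer(1)) > 0]
  to_impute <- to_impute[order(-vapply(na_idx[to_impute], length, integer(1)))]
  for (it in seq_len(max_iter)) {
    for (nm in to_impute) {
      obs_tr <- tr & !(seq_len(nrow(dat)) %in% na_idx[[nm]])
      if (sum(obs_tr) < 10) next
      fit <- ranger::ranger(
        x = as.data.frame(dat[obs_tr, setdiff(names(dat), nm), drop = FALSE]),
        y = dat[[nm]][obs_tr], num.trees = 50, seed = seed + it,
        num.threads = 1)
      pred <- predict(fit, data = as.data.frame(
        dat[na_idx[[nm]], setdiff(names(dat), nm), drop = FALSE]),
        num.threads = 1)$predictions
      dat[[nm]][na_idx[[nm]]] <- pred
    }
  }

  # one-hot encode factors, z-score numerics with training statistics
  out <- list()
  centers <- scales <- numeric(0)
  for (nm in names(dat)) {
    x <- dat[[nm]]
    if (is.factor(x)) {
      for (lv in levels(x)) {
        cn <- paste0(nm, "_", lv)
        out[[cn]] <- as.numeric(x == lv)
      }
    } else {
      mu <- mean(x[tr]); sg <- stats::sd(x[tr])
      if (!is.finite(sg) || sg < 1e-12) sg <- 1
      out[[nm]] <- (x - mu) / sg
      centers[nm] <- mu; scales[nm] <- sg
    }
  }
  res <- bind_cols(tibble(patient_id = ids), as_tibble(out))
  attr(res, "dropped_columns") <- dropped
  attr(res, "centers") <- centers
  attr(res, "scales") <- scales
  attr(res, "provenance") <- list(train_ids = train_ids, seed = seed)
  res
}

#' Split a cohort into training and hold-out patients
#'
#' Patients (never rows) are assigned to a fold, preventing leakage of a
#' patient's intervals across folds. With `stratify`, the split is done
#' within each stratum so event rates balance.
#'
#' @param patient_ids Character vector of unique patient ids (or a tibble
#'   with a `patient_id` column).
#' @param ratio Training fraction (0.8).
#' @param seed Integer seed.
#' @param stratify Optional vector (same length/order as `patient_ids`) to
#'   stratify on, e.g. the event indicator.
#' @return List with `train` and `test` id vectors.
#' @export
split_cohort <- function(patient_ids, ratio = 0.8, seed = 1L,
                         stratify = NULL) {
  if (is.data.frame(patient_ids)) patient_ids <- patient_ids$patient_id
  stopifnot(!anyDuplicated(patient_ids))
  if (length(patient_ids) < 5)
    stop("need at least 5 patients to split", call. = FALSE)
  set.seed(seed)
  if (is.null(stratify)) stratify <- rep(1L, length(patient_ids))
  train <- character(0)
  for (s in unique(stratify)) {
    ids <- patient_ids[stratify == s]
    n_tr <- round(ratio * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(patient_ids, train)))
}

#' Restructure a cohort into 90-day person-period rows (CPIUs)
#'
#' Each patient contributes one row per 90-day interval from day 0 until
#' event or censoring. The final row carries the residual risk time and the
#' event indicator; an event or censoring falling exactly on an interval
#' boundary closes the previous interval (no zero-length rows). Features for
#' interval `k` are the latent codes of the most recent ECG recorded on or
#' before day `90 * k` (last value carried forward), optionally joined with
#' static baseline features.
#'
#' @param outcomes Tibble `(patient_id, follow_up_days, event, ...)`.
#' @param codes Tibble `(patient_id, day, AE0..)` of latent codes (or any
#'   time-varying features); every patient needs a day-0 row.
#' @param baseline_features Optional tibble `patient_id` + static features.
#' @param interval Interval width in days (90).
#' @return Tibble of person-period rows: `patient_id`, `k`,
#'   `interval_start`, `tau`, `d`, `ecg_day`, `ecg_age`, `carried`, then the
#'   time-varying and baseline features.
#' @export
build_cpius <- function(outcomes, codes, baseline_features = NULL,
                        interval = 90) {
  stopifnot(all(c("patient_id", "follow_up_days", "event") %in% names(outcomes)),
            all(c("patient_id", "day") %in% names(codes)))
  has_day0 <- codes |> group_by(.data$patient_id) |>
    summarise(d0 = any(.data$day == 0), .groups = "drop")
  missing0 <- setdiff(outcomes$patient_id,
                      has_day0$patient_id[has_day0$d0])
  if (length(missing0) > 0)
    stop("missing day-0 latent code for patient(s): ",
         paste(head(missing0, 5), collapse = ", "), call. = FALSE)

  fup <- outcomes$follow_up_days
  stopifnot(all(fup > 0))
  n_int <- ceiling(fup / interval)          # boundary: no zero-length rows
  rows <- tibble(
    patient_id = rep(outcomes$patient_id, n_int),
    d_pat = rep(outcomes$event, n_int),
    fup = rep(fup, n_int),
    k = unlist(lapply(n_int, function(m) 0:(m - 1)), use.names = FALSE)
  ) |>
    mutate(interval_start = .data$k * interval,
           tau = pmin(interval, .data$fup - .data$interval_start),
           d = as.integer(.data$d_pat == 1L &
                            .data$interval_start + interval >= .data$fup &
                            .data$tau <= interval))
  # d = 1 only on the final row of an event patient
  rows <- rows |>
    group_by(.data$patient_id) |>
    mutate(d = as.integer(.data$d_pat == 1L & .data$k == max(.data$k))) |>
    ungroup()

  feat_cols <- setdiff(names(codes), c("patient_id", "day"))
  codes <- codes |> arrange(.data$patient_id, .data$day)
  rows <- rows |> arrange(.data$patient_id, .data$k)
  # LVCF: index of the latest code with day <= interval start, per patient
  code_days <- split(codes$day, codes$patient_id)
  code_offset <- c(0, cumsum(vapply(code_days, length, integer(1))))
  names(code_offset) <- c(names(code_days), "_end")
  start_by_pat <- split(rows$interval_start, rows$patient_id)
  pick <- unlist(lapply(names(start_by_pat), function(pid) {
    code_offset[[pid]] + findInterval(start_by_pat[[pid]], code_days[[pid]])
  }), use.names = FALSE)
  rows$ecg_day <- codes$day[pick]
  rows <- bind_cols(rows, codes[pick, feat_cols, drop = FALSE]) |>
    mutate(ecg_age = .data$interval_start - .data$ecg_day,
           carried = .data$ecg_age > 0)
  out <- rows |>
    select("patient_id", "k", "interval_start", "tau", "d", "ecg_day",
           "ecg_age", "carried", dplyr::all_of(feat_cols))
  if (!is.null(baseline_features))
    out <- out |> left_join(baseline_features, by = "patient_id")
  out
}

#' Freeze a person-period table at its baseline feature values
#'
#' Replaces the named time-varying columns of every row by the patient's
#' `k = 0` values (and zeroes the ECG age), producing the static-comparator
#' dataset: identical machinery, baseline-frozen features.
#'
#' @param rows Person-period tibble from [build_cpius()].
#' @param dynamic_cols Columns to freeze; defaults to the `AE*` latents.
#' @return Tibble of the same shape.
#' @export
freeze_baseline <- function(rows, dynamic_cols = NULL) {
  dynamic_cols <- dynamic_cols %||% grep("^AE", names(rows), value = TRUE)
  base0 <- rows |> filter(.data$k == 0) |>
    select("patient_id", dplyr::all_of(dynamic_cols))
  rows |>
    select(-dplyr::all_of(dynamic_cols)) |>
    left_join(base0, by = "patient_id") |>
    mutate(ecg_day = 0, ecg_age = 0, carried = .data$k > 0) |>
    select(dplyr::all_of(names(rows)))
}
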