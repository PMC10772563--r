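#' Time-specific AUROC within one interval
#'
#' `AUROC = P(p_case > p_control) + 0.5 * P(tie)` over the at-risk rows of
#' the interval (Mann-Whitney convention), computed from ranks.
#'
#' @param p Predicted event probabilities (or any monotone risk score).
#' @param d Observed event indicators (0/1).
#' @return Scalar AUROC, or `NA` if the interval has no case or no control.
#' @export
time_specific_auroc <- function(p, d) {
  stopifnot(length(p) == length(d))
  keep <- is.finite(p) & !is.na(d)
  p <- p[keep]; d <- d[keep]
  n1 <- sum(d == 1); n0 <- sum(d == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[d == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-interval AUROC table
#'
#' Intervals with fewer than `min_events` events or `min_controls`
#' non-events are flagged invalid and excluded from the time-varying mean.
#'
#' @param rows Person-period tibble with predictions (`.p`) and outcomes
#'   (`d`), e.g. from [predict_hazard()].
#' @param min_events,min_controls Degenerate-interval thresholds.
#' @return Tibble `(k, n_at_risk, n_events, auroc, valid)`.
#' @export
interval_auroc <- function(rows, min_events = 2, min_controls = 2) {
  stopifnot(all(c("k", ".p", "d") %in% names(rows)))
  rows |>
    group_by(.data$k) |>
    summarise(n_at_risk = dplyr::n(),
              n_events = sum(.data$d),
              auroc = time_specific_auroc(.data$.p, .data$d),
              .groups = "drop") |>
    mutate(valid = .data$n_events >= min_events &
             (.data$n_at_risk - .data$n_events) >= min_controls &
             !is.na(.data$auroc)) |>
    arrange(.data$k)
}

#' Mean time-varying AUROC over the evaluation horizon
#'
#' Unweighted mean and SD of the valid time-specific AUROCs up to the
#' horizon (16 intervals of 90 days = 48 months).
#'
#' @param x Either a prediction tibble (with `k`, `.p`, `d`) or an
#'   [interval_auroc()] table.
#' @param horizon Number of intervals included.
#' @param min_events,min_controls Passed to [interval_auroc()].
#' @return List with `mean`, `sd`, `n_intervals` and the interval `table`.
#' @export
mean_time_varying_auroc <- function(x, horizon = 16, min_events = 2,
                                    min_controls = 2) {
  tab <- if (all(c("auroc", "valid") %in% names(x))) x
  else interval_auroc(x, min_events, min_controls)
  tab <- tab |> filter(.data$k < horizon)
  ok <- tab$auroc[tab$valid]
  if (length(ok) == 0) stop("no valid intervals within the horizon",
                            call. = FALSE)
  list(mean = mean(ok), sd = stats::sd(ok), n_intervals = length(ok),
       table = tab)
}

#' Percentile bootstrap CI by patient resampling
#'
#' Unique patients are drawn with replacement (all of a patient's rows enter
#' together); the statistic is recomputed on each resample and the 2.5/97.5
#' percentiles returned.
#'
#' @param rows Tibble with a `patient_id` column.
#' @param statistic Function taking a resampled tibble, returning a scalar.
#' @param n_boot Number of bootstrap iterations (500).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Tibble `(estimate, conf.low, conf.high, n_boot)`; the bootstrap
#'   draws are attached as attribute `"draws"`.
#' @export
bootstrap_ci <- function(rows, statistic, n_boot = 500, seed = 1L,
                         level = 0.95) {
  pats <- unique(rows$patient_id)
  if (length(pats) < 2) stop("need at least 2 patients", call. = FALSE)
  set.seed(seed)
  by_pat <- split(seq_len(nrow(rows)), rows$patient_id)
  draws <- vapply(seq_len(n_boot), function(b) {
    bp <- sample(pats, length(pats), replace = TRUE)
    idx <- by_pat[bp]
    rs <- rows[unlist(idx, use.names = FALSE), , drop = FALSE]
    # relabel draws so a patient sampled twice enters as two pseudo-patients
    rs$patient_id <- rep(paste0(bp, "#", seq_along(bp)), lengths(idx))
    statistic(rs)
  }, numeric(1))
  alpha <- (1 - level) / 2
  out <- tibble(estimate = statistic(rows),
                conf.low = quantile(draws, alpha, names = FALSE, na.rm = TRUE),
                conf.high = quantile(draws, 1 - alpha, names = FALSE, na.rm = TRUE),
                n_boot = n_boot)
  attr(out, "draws") <- draws
  out
}

#' Decile calibration table
#'
#' Rows are ranked by predicted probability and cut into 10 equal-count
#' groups; tied predictions stay in the same group (so group counts can
#' differ by the tie-group size). Per group the mean prediction and the
#' observed event rate are reported. If every prediction is identical a
#' single group is returned.
#'
#' @param p Predicted probabilities.
#' @param d Observed event indicators.
#' @param n_groups Number of risk groups (10).
#' @return Tibble `(decile, n, mean_predicted, observed_rate)`.
#' @export
calibration_deciles <- function(p, d, n_groups = 10) {
  stopifnot(length(p) == length(d))
  if (length(p) < n_groups)
    stop("need at least ", n_groups, " rows", call. = FALSE)
  r <- rank(p, ties.method = "average")   # average ranks keep ties together
  br <- unique(quantile(r, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- if (length(br) <= 2) rep(1L, length(p))
  else cut(r, breaks = br, include.lowest = TRUE, labels = FALSE)
  tibble(decile = grp, p = p, d = d) |>
    group_by(.data$decile) |>
    summarise(n = dplyr::n(),
              mean_predicted = mean(.data$p),
              observed_rate = mean(.data$d),
              .groups = "drop") |>
    arrange(.data$decile)
}

#' Calibration slope of observed on predicted decile rates
#'
#' @param calib Table from [calibration_deciles()].
#' @return Slope of the least-squares line through
#'   `(mean_predicted, observed_rate)`.
#' @export
calibration_slope <- function(calib) {
  unname(coef(lm(observed_rate ~ mean_predicted, data = calib))[2])
}

#' Permutation feature importance of a hazard forest
#'
#' For each feature, its column is shuffled across the test rows and the
#' mean time-varying AUROC recomputed; the importance is the baseline AUROC
#' minus the permuted AUROC, averaged over `repeats` shuffles.
#'
#' @param forest A fitted [fit_hazard_forest()] model.
#' @param rows Test person-period rows.
#' @param features Features to permute; defaults to the forest's features.
#' @param repeats Shuffles per feature (5).
#' @param seed Integer seed.
#' @param horizon Evaluation horizon (intervals).
#' @return Importance table: tibble `(feature, importance, values)` sorted
#'   by decreasing mean importance, `values` holding the per-repeat drops;
#'   baseline AUROC in attribute `"baseline"`.
#' @export
permutation_importance <- function(forest, rows, features = NULL,
                                   repeats = 5, seed = 1L, horizon = 16) {
  features <- features %||% forest$features
  unknown <- setdiff(features, names(rows))
  if (length(unknown) > 0)
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- mean_time_varying_auroc(predict_hazard(forest, rows),
                                  horizon = horizon)$mean
  set.seed(seed)
  out <- purrr::map_dfr(features, function(f) {
    drops <- vapply(seq_len(repeats), function(r) {
      perm <- rows
      perm[[f]] <- sample(perm[[f]])
      base - mean_time_varying_auroc(predict_hazard(forest, perm),
                                     horizon = horizon)$mean
    }, numeric(1))
    tibble(feature = f, importance = mean(drops), values = list(drops))
  })
  out <- out |> arrange(dplyr::desc(.data$importance))
  attr(out, "baseline") <- base
  attr(out, "repeats") <- repeats
  out
}

#' Subgroup (fairness) performance
#'
#' Mean time-varying AUROC computed separately within each level of a
#' grouping column (e.g. sex, ischaemic cardiomyopathy), with group sizes;
#' groups with no valid interval are flagged with `NA`.
#'
#' @param rows Prediction tibble with `.p`, `d`, `k` and the grouping
#'   column.
#' @param group_col Name of the grouping column.
#' @param horizon Evaluation horizon (intervals).
#' @return Tibble `(group, n_patients, n_rows, auroc_mean, auroc_sd)`.
#' @export
subgroup_performance <- function(rows, group_col, horizon = 16) {
  stopifnot(group_col %in% names(rows))
  rows |>
    group_by(group = .data[[group_col]]) |>
    group_modify(function(g, key) {
      res <- tryCatch(mean_time_varying_auroc(g, horizon = horizon),
                      error = function(e) NULL)
      tibble(n_patients = dplyr::n_distinct(g$patient_id),
             n_rows = nrow(g),
             auroc_mean = if (is.null(res)) NA_real_ else res$mean,
             auroc_sd = if (is.null(res)) NA_real_ else res$sd)
    }) |>
    ungroup()
}

#' Full evaluation report for a fitted hazard forest
#'
#' @param forest A fitted model.
#' @param rows Hold-out person-period rows.
#' @param horizon Evaluation horizon (intervals).
#' @param n_boot Bootstrap iterations for the CI of the mean time-varying
#'   AUROC (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `eval_report`: list with the per-interval AUROC
#'   table, mean +/- sd, calibration table and optional bootstrap CI.
#' @export
evaluate_model <- function(forest, rows, horizon = 16, n_boot = 0, seed = 1L) {
  pr <- predict_hazard(forest, rows)
  mt <- mean_time_varying_auroc(pr, horizon = horizon)
  calib <- calibration_deciles(pr$.p, pr$d)
  ci <- NULL
  if (n_boot > 0) {
    ci <- bootstrap_ci(pr, function(rw)
      tryCatch(mean_time_varying_auroc(rw, horizon = horizon)$mean,
               error = function(e) NA_real_),
      n_boot = n_boot, seed = seed)
  }
  structure(list(intervals = mt$table, auroc_mean = mt$mean,
                 auroc_sd = mt$sd, n_valid_intervals = mt$n_intervals,
                 calibration = calib, bootstrap = ci, horizon = horizon,
                 model_type = forest$type, predictions = pr),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s model: mean time-varying AUROC %.3f +/- %.3f over %d valid intervals (horizon %d)\n",
    x$model_type, x$auroc_mean, x$auroc_sd, x$n_valid_intervals, x$horizon))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f] (%d resamples)\n",
                x$bootstrap$conf.low, x$bootstrap$conf.high,
                x$bootstrap$n_boot))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$intervals

#' @export
glance.eval_report <- function(x, ...) {
  tibble(model_type = x$model_type, auroc_mean = x$auroc_mean,
         auroc_sd = x$auroc_sd, n_valid_intervals = x$n_valid_intervals,
         conf.low = if (is.null(x$bootstrap)) NA_real_ else x$bootstrap$conf.low,
         conf.high = if (is.null(x$bootstrap)) NA_real_ else x$bootstrap$conf.high,
         calibration_slope = calibration_slope(x$calibration))
}

#' Write an evaluation report to plain-text files
#'
#' @param report An [evaluate_model()] result.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$intervals, file.path(dir, "interval_auroc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$calibration, file.path(dir, "calibration.csv"),
                   row.names = FALSE)
  js <- list(model_type = report$model_type, auroc_mean = report$auroc_mean,
             auroc_sd = report$auroc_sd,
             n_valid_intervals = report$n_valid_intervals,
             horizon = report$horizon)
  if (!is.null(report$bootstrap))
    js$bootstrap_ci <- c(report$bootstrap$conf.low, report$bootstrap$conf.high)
  path <- file.path(dir, "eval_report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
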