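#' Poisson split gain for a candidate node split
#'
#' The gain is the improvement in Poisson log-likelihood of the interval
#' event counts with a log-risk-time offset:
#' `sum_c D_c * log(D_c / T_c) - D * log(D / T)` over the two children, with
#' `0 * log(0) == 0`. It is non-negative for every admissible split.
#'
#' @param d Event indicators (0/1) of the rows at the node.
#' @param tau Risk times of the rows (days).
#' @param left Logical vector marking the rows sent to the left child.
#' @return Scalar gain.
#' @export
poisson_split_gain <- function(d, tau, left) {
  stopifnot(length(d) == length(tau), length(left) == length(d))
  if (!any(left) || all(left))
    stop("both children must be non-empty", call. = FALSE)
  f <- function(D, T) if (D > 0 && T > 0) D * log(D / T) else 0
  TL <- sum(tau[left]); TR <- sum(tau[!left])
  if (TL <= 0 || TR <= 0)
    stop("split invalid: child with zero risk time", call. = FALSE)
  f(sum(d[left]), TL) + f(sum(d[!left]), TR) - f(sum(d), sum(tau))
}

forest_design <- function(rows, features) {
  X <- as.matrix(rows[, features, drop = FALSE])
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  storage.mode(X) <- "double"
  X
}

#' Fit a Poisson-splitting hazard forest on person-period rows
#'
#' Each tree is grown on a patient-level bootstrap resample (all of a
#' patient's rows enter together). At every node `mtry` candidate features
#' are examined and the split with the largest Poisson log-likelihood gain
#' is taken; growth stops when no admissible split remains (each child must
#' hold at least `min_events` events and `min_obs` rows). Leaves store the
#' Bayes-smoothed hazard `lambda = (D + a) / (T + b)` with `a = r0 * b`,
#' where `r0` is the tree's root event rate, so the prior mean equals the
#' marginal hazard.
#'
#' @param rows Person-period tibble from [build_cpius()] with columns `d`
#'   and `tau`.
#' @param features Feature column names; defaults to every numeric column
#'   except the bookkeeping ones.
#' @param n_trees Number of trees.
#' @param mtry Features tried per node; default `floor(sqrt(p))`.
#' @param min_events Minimum events per child (terminal-node event size).
#' @param min_obs Minimum rows per child.
#' @param prior_b Prior strength `b` in days of pseudo-risk-time (one CPIU).
#' @param seed Integer seed (bootstrap and feature sampling).
#' @return Object of class `hazard_forest`.
#' @export
fit_hazard_forest <- function(rows, features = NULL, n_trees = 300,
                              mtry = NULL, min_events = 5, min_obs = 10,
                              prior_b = 90, seed = 1L) {
  stopifnot(all(c("patient_id", "d", "tau") %in% names(rows)),
            nrow(rows) > 0)
  if (sum(rows$d) == 0)
    stop("cannot fit a hazard forest with zero events", call. = FALSE)
  features <- features %||% setdiff(
    names(rows)[vapply(rows, is.numeric, logical(1))],
    c("k", "interval_start", "tau", "d", "ecg_day", "ecg_age"))
  X <- forest_design(rows, features)
  mtry <- mtry %||% max(1L, floor(sqrt(length(features))))
  d <- as.integer(rows$d)
  tau <- as.numeric(rows$tau)
  pid <- rows$patient_id
  pat_rows <- split(seq_along(pid) - 1L, pid)   # 0-based rows per patient
  pats <- names(pat_rows)
  set.seed(seed)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot_p <- sample(pats, length(pats), replace = TRUE)
    idx <- unlist(pat_rows[boot_p], use.names = FALSE)
    r0 <- sum(d[idx + 1L]) / sum(tau[idx + 1L])
    a <- r0 * prior_b
    trees[[t]] <- grow_tree_cpp(X, d, tau, idx, as.integer(mtry),
                                min_events, as.integer(min_obs), a, prior_b)
  }
  structure(list(trees = trees, features = features, n_trees = n_trees,
                 mtry = mtry, min_events = min_events, min_obs = min_obs,
                 prior_b = prior_b, seed = seed,
                 marginal_rate = sum(d) / sum(tau),
                 provenance = list(train_patients = pats),
                 type = "dynamic"),
            class = "hazard_forest")
}

#' @export
print.hazard_forest <- function(x, ...) {
  nl <- vapply(x$trees, function(t) sum(t$feature < 0), integer(1))
  cat(sprintf(
    "<hazard_forest> %s, %d trees (mean %.1f leaves), mtry %d, min events %g, prior b = %g days\n",
    x$type, x$n_trees, mean(nl), x$mtry, x$min_events, x$prior_b))
  invisible(x)
}

#' Predict per-row hazards and interval event probabilities
#'
#' The hazard is the mean of the reached leaves' Bayes rates across trees;
#' the event probability is `p = 1 - exp(-lambda * tau_hat)` with `tau_hat`
#' the planned risk time (90 days for prospective prediction).
#'
#' @param forest A [fit_hazard_forest()] model.
#' @param rows Person-period tibble with the training feature schema.
#' @param tau_planned Planned risk time per row (days).
#' @return `rows` with columns `.lambda` and `.p` appended.
#' @export
predict_hazard <- function(forest, rows, tau_planned = 90) {
  stopifnot(inherits(forest, "hazard_forest"))
  missing_f <- setdiff(forest$features, names(rows))
  if (length(missing_f) > 0)
    stop("feature schema mismatch; missing: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  X <- forest_design(rows, forest$features)
  lam <- predict_forest_cpp(forest$trees, X)
  rows$.lambda <- as.numeric(lam)
  rows$.p <- 1 - exp(-rows$.lambda * tau_planned)
  rows
}

#' Fit the baseline-frozen static comparator
#'
#' Identical forest machinery, but every row's time-varying features are
#' replaced by the patient's day-0 values first (see [freeze_baseline()]),
#' isolating the effect of the time-varying features.
#'
#' @inheritParams fit_hazard_forest
#' @param dynamic_cols Columns to freeze at baseline (default the `AE*`
#'   latents).
#' @return A `hazard_forest` with `type = "static"`.
#' @export
fit_static_model <- function(rows, features = NULL, dynamic_cols = NULL,
                             n_trees = 300, mtry = NULL, min_events = 5,
                             min_obs = 10, prior_b = 90, seed = 1L) {
  frozen <- freeze_baseline(rows, dynamic_cols)
  f <- fit_hazard_forest(frozen, features = features, n_trees = n_trees,
                         mtry = mtry, min_events = min_events,
                         min_obs = min_obs, prior_b = prior_b, seed = seed)
  f$type <- "static"
  f
}

#' Tune forest hyperparameters by patient-level 5-fold cross-validation
#'
#' Patients are partitioned into folds; for each grid point the forest is
#' fit on the in-fold patients and scored by the mean time-varying AUROC on
#' the out-of-fold rows. Ties break toward smaller forests (fewer trees,
#' then smaller mtry).
#'
#' @param rows Person-period training rows.
#' @param grid Tibble of hyperparameter combinations (columns among
#'   `n_trees`, `mtry`, `min_events`).
#' @param features Feature columns (see [fit_hazard_forest()]).
#' @param n_folds Number of CV folds.
#' @param seed Integer seed.
#' @param horizon Evaluation horizon in intervals.
#' @return The winning grid row; the full CV table is attached as attribute
#'   `"cv_results"`.
#' @export
tune_hyperparams <- function(rows, grid, features = NULL, n_folds = 5,
                             seed = 1L, horizon = 16) {
  stopifnot(nrow(grid) >= 1)
  set.seed(seed)
  pats <- unique(rows$patient_id)
  fold <- sample(rep_len(seq_len(n_folds), length(pats)))
  names(fold) <- pats
  res <- grid
  res$cv_auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- rows[fold[rows$patient_id] != f, , drop = FALSE]
      te <- rows[fold[rows$patient_id] == f, , drop = FALSE]
      fit <- fit_hazard_forest(
        tr, features = features,
        n_trees = grid$n_trees[g] %||% 100,
        mtry = grid$mtry[g],
        min_events = grid$min_events[g] %||% 5,
        seed = seed + 100 * g + f)
      pr <- predict_hazard(fit, te)
      aucs[f] <- mean_time_varying_auroc(pr, horizon = horizon)$mean
    }
    res$cv_auroc[g] <- mean(aucs, na.rm = TRUE)
  }
  ord <- order(-res$cv_auroc,
               res$n_trees %||% rep(0, nrow(res)),
               res$mtry %||% rep(0, nrow(res)))
  best <- res[ord[1], , drop = FALSE]
  attr(best, "cv_results") <- res
  attr(best, "fold_assignment") <- fold
  best
}

#' @export
tidy.hazard_forest <- function(x, ...) {
  purrr::imap_dfr(x$trees, function(t, i)
    tibble(tree = i, n_nodes = length(t$feature),
           n_leaves = sum(t$feature < 0),
           depth_events = max(t$D), root_rate = t$D[1] / t$T[1]))
}

#' @export
glance.hazard_forest <- function(x, ...) {
  nl <- vapply(x$trees, function(t) sum(t$feature < 0), integer(1))
  tibble(type = x$type, n_trees = x$n_trees, mtry = x$mtry,
         min_events = x$min_events, prior_b = x$prior_b,
         mean_leaves = mean(nl), marginal_rate = x$marginal_rate)
}

#' Fit a time-varying Cox proportional hazards model on person-period rows
#'
#' Rows are converted to counting-process `(start, stop, event)` form
#' (`start = interval_start`, `stop = interval_start + tau`) and fit with
#' [survival::coxph()]. This stage is standard inference and is delegated to
#' the survival package. Non-convergence is reported as a warning on the
#' result, never silently ignored.
#'
#' @param rows Person-period tibble from [build_cpius()].
#' @param features Covariate columns; defaults to the numeric feature
#'   columns.
#' @return Object of class `cox_result`: tidy tibble (term, HR, CI, p) with
#'   the fit attached.
#' @export
fit_time_varying_cox <- function(rows, features = NULL) {
  features <- features %||% setdiff(
    names(rows)[vapply(rows, is.numeric, logical(1))],
    c("k", "interval_start", "tau", "d", "ecg_day", "ecg_age"))
  dat <- rows |>
    mutate(.start = .data$interval_start,
           .stop = .data$interval_start + .data$tau,
           .event = .data$d) |>
    select(".start", ".stop", ".event", dplyr::all_of(features))
  fml <- stats::as.formula(paste(
    "survival::Surv(.start, .stop, .event) ~",
    paste(sprintf("`%s`", features), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = as.data.frame(dat)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  out <- tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    conf.low = s$conf.int[, "lower .95"],
    conf.high = s$conf.int[, "upper .95"],
    p.value = s$coefficients[, "Pr(>|z|)"]
  )
  structure(out, class = c("cox_result", class(out)),
            fit = fit, convergence_warning = warn)
}

#' @export
tidy.cox_result <- function(x, ...) as_tibble(x)

#' @export
glance.cox_result <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(n = fit$n, n_events = fit$nevent,
         logLik = as.numeric(stats::logLik(fit)),
         concordance = as.numeric(fit$concordance["concordance"]),
         converged = is.null(attr(x, "convergence_warning")))
}
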