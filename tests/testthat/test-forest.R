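test_that("Poisson split gain matches direct likelihood evaluation", {
  # children with identical event rates: no improvement
  d <- c(1, 0, 1, 0); tau <- c(50, 50, 50, 50)
  expect_equal(poisson_split_gain(d, tau, c(TRUE, TRUE, FALSE, FALSE)), 0,
               tolerance = 1e-12)

  # node (D=4, T=400) split into (4, 100) and (0, 300): direct formula
  d2 <- c(rep(1, 4), rep(0, 6))
  tau2 <- c(rep(25, 4), rep(50, 6))
  left <- c(rep(TRUE, 4), rep(FALSE, 6))
  direct <- 4 * log(4 / 100) - 4 * log(4 / 400)   # 0*log0 term drops
  expect_equal(poisson_split_gain(d2, tau2, left), direct, tolerance = 1e-12)

  # likelihood-ratio non-negativity over random admissible splits
  set.seed(3)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    dd <- rbinom(n, 1, 0.3)
    tt <- runif(n, 1, 90)
    lf <- seq_len(n) %in% sample(n, sample(1:(n - 1), 1))
    expect_gte(poisson_split_gain(dd, tt, lf), -1e-12)
  }

  expect_error(poisson_split_gain(d, tau, rep(TRUE, 4)), "non-empty")
  expect_error(poisson_split_gain(c(1, 0), c(10, 0), c(FALSE, TRUE)),
               "zero risk time")
})

test_that("every leaf satisfies lambda * (T + b) = D + a", {
  rows <- two_rate_cohort(5, n = 300, horizon = 720)
  f <- fit_hazard_forest(rows, features = c("xbin", "noise1", "noise2"),
                         n_trees = 20, seed = 2, prior_b = 90)
  for (tr in f$trees) {
    r0 <- tr$D[1] / tr$T[1]
    a <- r0 * f$prior_b
    leaves <- which(tr$feature < 0)
    expect_equal(tr$lambda[leaves] * (tr$T[leaves] + f$prior_b),
                 tr$D[leaves] + a, tolerance = 1e-9)
    expect_true(all(tr$lambda[leaves] > 0))
  }
})

test_that("a degenerate single-leaf tree returns the Bayes-smoothed marginal rate", {
  rows <- two_rate_cohort(6, n = 200, horizon = 720)
  f <- fit_hazard_forest(rows, features = "noise1", n_trees = 1, mtry = 1,
                         min_events = 1e9, prior_b = 90, seed = 3)
  tr <- f$trees[[1]]
  expect_equal(length(tr$feature), 1L)
  D <- tr$D[1]; Tt <- tr$T[1]; r0 <- D / Tt
  expect_equal(predict_hazard(f, rows[1, ])$.lambda,
               (D + r0 * 90) / (Tt + 90), tolerance = 1e-12)
})

test_that("forest prediction equals independent rule-following tree traversal", {
  rows <- two_rate_cohort(7, n = 400, horizon = 720)
  f <- fit_hazard_forest(rows, features = c("xbin", "noise1", "noise2"),
                         n_trees = 30, seed = 4)
  X <- as.matrix(rows[, f$features])
  traverse_oracle <- function(tr, x) {
    node <- 1L
    while (tr$feature[node] >= 0) {
      node <- if (x[tr$feature[node] + 1L] <= tr$threshold[node])
        tr$left[node] + 1L else tr$right[node] + 1L
    }
    tr$lambda[node]
  }
  set.seed(5)
  idx <- sample(nrow(X), 1000, replace = TRUE)
  manual <- vapply(idx, function(i)
    mean(vapply(f$trees, traverse_oracle, numeric(1), x = X[i, ])),
    numeric(1))
  pred <- predict_hazard(f, rows[idx, ])$.lambda
  expect_equal(pred, manual, tolerance = 1e-12)
})

test_that("hazard predictions follow the closed-form probability map", {
  rows <- two_rate_cohort(8, n = 150, horizon = 360)
  f <- fit_hazard_forest(rows, features = c("xbin", "noise1"), n_trees = 10,
                         seed = 1)
  pr <- predict_hazard(f, rows, tau_planned = 90)
  expect_equal(pr$.p, 1 - exp(-pr$.lambda * 90), tolerance = 1e-12)
  # lambda * tau = ln 2 -> p = 0.5; p monotone in lambda
  expect_equal(1 - exp(-log(2) / 90 * 90), 0.5)
  o <- order(pr$.lambda)
  expect_true(all(diff(pr$.p[o]) >= 0))
  expect_error(predict_hazard(f, rows[, c("patient_id", "tau", "d")]),
               "schema mismatch")
  expect_error(fit_hazard_forest(dplyr::mutate(rows, d = 0L)), "zero events")
})

test_that("averaging more trees shrinks spurious structure under pure noise", {
  set.seed(9)
  n <- 400
  oc <- dplyr::tibble(patient_id = sprintf("P%04d", 1:n),
                      follow_up_days = pmin(ceiling(rexp(n, 0.004)), 720),
                      event = as.integer(rexp(n, 0.004) <= 720))
  oc$event <- as.integer(stats::runif(n) < 0.4)    # outcome independent of x
  cd <- dplyr::tibble(patient_id = oc$patient_id, day = 0,
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  rows <- build_cpius(oc, cd)
  marg <- sum(rows$d) / sum(rows$tau)
  dev <- vapply(c(10, 200), function(nt) {
    f <- fit_hazard_forest(rows, features = c("n1", "n2", "n3"),
                           n_trees = nt, seed = 10)
    te <- two_rate_cohort(11, n = 200, horizon = 720)
    te$n1 <- rnorm(nrow(te)); te$n2 <- rnorm(nrow(te)); te$n3 <- rnorm(nrow(te))
    mean(abs(predict_hazard(f, te)$.lambda - marg))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
})

test_that("hyperparameter tuning respects fold structure and singleton grids", {
  rows <- two_rate_cohort(12, n = 300, horizon = 720)
  grid1 <- dplyr::tibble(n_trees = 30, mtry = 2, min_events = 10)
  best <- tune_hyperparams(rows, grid1, features = c("xbin", "noise1"),
                           seed = 2, n_folds = 3)
  expect_equal(best$n_trees, 30)
  fold <- attr(best, "fold_assignment")
  expect_setequal(names(fold), unique(rows$patient_id))
  expect_true(all(table(names(fold)) == 1))

  grid2 <- dplyr::tibble(n_trees = c(20, 40), mtry = c(1, 3),
                         min_events = c(10, 10))
  best2 <- tune_hyperparams(rows, grid2, features = c("xbin", "noise1", "noise2"),
                            seed = 3, n_folds = 3)
  cv <- attr(best2, "cv_results")
  expect_equal(nrow(cv), 2)
  expect_equal(best2$cv_auroc, max(cv$cv_auroc))
})

test_that("the static comparator freezes features through the same machinery", {
  co <- simulate_cohort(200, seed = 14)
  cd <- visit_t_amp(co)
  rows <- build_cpius(co$outcomes, cd)
  sta <- fit_static_model(rows, dynamic_cols = "t_amp", n_trees = 20, seed = 5)
  expect_equal(sta$type, "static")
  expect_identical(sta$features, fit_hazard_forest(rows, n_trees = 1,
                                                   seed = 1)$features)
})

test_that("time-varying Cox recovers planted effects and scales as a likelihood", {
  set.seed(16)
  n <- 800
  x <- rnorm(n)
  lam <- 0.002 * exp(0.3 * x)
  et <- rexp(n, lam)
  oc <- dplyr::tibble(patient_id = sprintf("P%04d", 1:n),
                      follow_up_days = pmin(ceiling(et), 1440),
                      event = as.integer(et <= 1440))
  cd <- dplyr::tibble(patient_id = oc$patient_id, day = 0, xvar = x)
  rows <- build_cpius(oc, cd)
  res <- fit_time_varying_cox(rows, features = "xvar")
  expect_true(res$conf.low[1] <= exp(0.3) && exp(0.3) <= res$conf.high[1])
  expect_true(all(res$hr > 0))
  expect_true(all(res$conf.low <= res$hr & res$hr <= res$conf.high))

  # duplicating the data leaves the HR fixed and narrows the CI
  rows2 <- dplyr::bind_rows(rows, dplyr::mutate(rows, patient_id = paste0(patient_id, "_b")))
  res2 <- fit_time_varying_cox(rows2, features = "xvar")
  expect_equal(res2$hr[1], res$hr[1], tolerance = 1e-3)  # solver tolerance
  expect_lt(res2$conf.high[1] - res2$conf.low[1],
            res$conf.high[1] - res$conf.low[1])
})

test_that("Cox confidence intervals achieve nominal null coverage", {
  cover <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 400
    x <- rnorm(n)
    et <- rexp(n, 0.002)                     # x has zero true effect
    oc <- dplyr::tibble(patient_id = sprintf("P%04d", 1:n),
                        follow_up_days = pmin(ceiling(et), 1440),
                        event = as.integer(et <= 1440))
    cd <- dplyr::tibble(patient_id = oc$patient_id, day = 0, xvar = x)
    res <- fit_time_varying_cox(build_cpius(oc, cd), features = "xvar")
    res$conf.low[1] <= 1 && 1 <= res$conf.high[1]
  }, logical(1))
  expect_gte(sum(cover), 16)   # 95% nominal; binomial slack at 20 replicates
})
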