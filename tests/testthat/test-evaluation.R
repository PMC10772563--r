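test_that("time-specific AUROC matches closed forms and the pairwise oracle", {
  expect_equal(time_specific_auroc(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(time_specific_auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(time_specific_auroc(runif(5), rep(1, 5))))

  auroc_oracle <- function(p, d) {
    cases <- p[d == 1]; controls <- p[d == 0]
    s <- 0
    for (a in cases) for (b in controls)
      s <- s + (a > b) + 0.5 * (a == b)
    s / (length(cases) * length(controls))
  }
  set.seed(4)
  for (i in 1:200) {
    p <- sample(seq(0, 1, 0.05), 50, replace = TRUE)  # ties guaranteed
    d <- rbinom(50, 1, 0.3)
    if (sum(d) %in% c(0, 50)) next
    expect_equal(time_specific_auroc(p, d), auroc_oracle(p, d),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(5)
  p <- runif(200); d <- rbinom(200, 1, 0.4)
  a0 <- time_specific_auroc(p, d)
  expect_equal(time_specific_auroc(qlogis(p), d), a0, tolerance = 1e-12)
  expect_equal(time_specific_auroc(p^3 + 2, d), a0, tolerance = 1e-12)
})

test_that("time-specific AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  p <- runif(300); d <- rbinom(300, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(d, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(time_specific_auroc(p, d), ref, tolerance = 1e-10)
})

test_that("mean time-varying AUROC summarises valid intervals only", {
  tab <- dplyr::tibble(k = 0:3, n_at_risk = c(100, 100, 100, 3),
                       n_events = c(10, 10, 1, 1),
                       auroc = c(0.6, 0.8, 0.9, 0.2),
                       valid = c(TRUE, TRUE, FALSE, FALSE))
  res <- mean_time_varying_auroc(tab)
  expect_equal(res$mean, 0.7)
  expect_equal(res$sd, sd(c(0.6, 0.8)))
  expect_equal(res$n_intervals, 2)

  same <- dplyr::mutate(tab[1:2, ], auroc = 0.7)
  expect_equal(mean_time_varying_auroc(same)$sd, 0)
  expect_error(mean_time_varying_auroc(dplyr::mutate(tab, valid = FALSE)),
               "no valid intervals")

  rows <- dplyr::tibble(patient_id = rep(c("A", "B", "C", "D"), each = 2),
                        k = rep(0:1, 4),
                        .p = c(0.9, 0.9, 0.8, 0.8, 0.1, 0.1, 0.2, 0.2),
                        d = c(0, 1, 0, 1, 0, 0, 0, 0))
  tab2 <- interval_auroc(rows)
  expect_equal(tab2$auroc[tab2$k == 1], 1)
  expect_false(tab2$valid[tab2$k == 0])    # no events in interval 0
})

test_that("patient bootstrap honours resampling structure and the CLT", {
  rows <- dplyr::tibble(patient_id = rep(sprintf("P%03d", 1:200), each = 2),
                        y = rep(rnorm(200), each = 2))
  ci_const <- bootstrap_ci(rows, function(d) 1, n_boot = 50, seed = 1)
  expect_equal(ci_const$conf.low, 1)
  expect_equal(ci_const$conf.high, 1)

  stat <- function(d) mean(tapply(d$y, d$patient_id, mean))
  ci <- bootstrap_ci(rows, stat, n_boot = 500, seed = 2)
  width <- ci$conf.high - ci$conf.low
  pat_means <- tapply(rows$y, rows$patient_id, mean)
  clt_width <- 2 * 1.96 * sd(pat_means) / sqrt(200)
  expect_lt(abs(width / clt_width - 1), 0.25)
  ci_rep <- bootstrap_ci(rows, stat, n_boot = 500, seed = 2)
  expect_identical(ci, ci_rep)
  expect_error(bootstrap_ci(rows[1:2, ], stat), "at least 2")
})

test_that("bootstrap CI contains the point estimate in most replicates", {
  inside <- vapply(1:20, function(s) {
    set.seed(300 + s)
    rows <- dplyr::tibble(patient_id = sprintf("P%03d", 1:80), y = rnorm(80))
    stat <- function(d) mean(d$y)
    ci <- bootstrap_ci(rows, stat, n_boot = 200, seed = s)
    ci$conf.low <= ci$estimate && ci$estimate <= ci$conf.high
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("decile calibration groups ranks correctly and keeps ties together", {
  p <- rep(seq(0.05, 0.95, 0.1), each = 20)
  set.seed(7)
  d <- rbinom(length(p), 1, p)
  calib <- calibration_deciles(p, d)
  expect_equal(nrow(calib), 10)
  expect_equal(sum(calib$n), length(p))
  expect_true(all(calib$n == 20))          # tie groups stay intact
  expect_equal(calib$mean_predicted, seq(0.05, 0.95, 0.1), tolerance = 1e-12)

  # constructed perfect calibration: observed equals predicted exactly
  d_perf <- unlist(lapply(seq(0.05, 0.95, 0.1), function(q)
    rep(c(1, 0), c(round(q * 20), 20 - round(q * 20)))))
  calib_p <- calibration_deciles(p, d_perf)
  expect_equal(calib_p$observed_rate, calib_p$mean_predicted,
               tolerance = 1e-12)

  one <- calibration_deciles(rep(0.5, 50), rbinom(50, 1, 0.5))
  expect_equal(nrow(one), 1)
  expect_error(calibration_deciles(runif(5), rbinom(5, 1, 0.5)), "at least")
})

test_that("well-specified predictions give a near-unit calibration slope", {
  set.seed(8)
  p <- runif(5000, 0.02, 0.6)
  d <- rbinom(5000, 1, p)
  slope <- calibration_slope(calibration_deciles(p, d))
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("permutation importance is near zero for unused features and reproducible", {
  rows <- two_rate_cohort(21, n = 400, horizon = 720)
  rows$unused <- rnorm(nrow(rows))
  f <- fit_hazard_forest(rows, features = c("xbin", "noise1"), n_trees = 40,
                         seed = 6)
  # `unused` is not even in the model: importance must be ~0
  imp <- permutation_importance(f, rows, features = c("xbin", "unused"),
                                repeats = 5, seed = 7)
  expect_lt(abs(imp$importance[imp$feature == "unused"]), 0.005)
  expect_gt(imp$importance[imp$feature == "xbin"], 0.02)
  expect_equal(lengths(imp$values), c(5, 5))

  imp2 <- permutation_importance(f, rows, features = c("xbin", "unused"),
                                 repeats = 5, seed = 7)
  expect_identical(imp$importance, imp2$importance)
  expect_error(permutation_importance(f, rows, features = "nope"), "unknown")

  # no permutation can create discrimination beyond baseline
  base <- attr(imp, "baseline")
  expect_lt(sum(imp$importance), 2 * (base - 0.5) + 0.05)
})

test_that("subgroup performance flags degenerate groups and respects constants", {
  rows <- two_rate_cohort(22, n = 500, horizon = 720)
  f <- fit_hazard_forest(rows, features = c("xbin", "noise1"), n_trees = 40,
                         seed = 8)
  pr <- predict_hazard(f, rows)
  pr$grp <- ifelse(pr$noise1 > 0, "hi", "lo")
  sub <- subgroup_performance(pr, "grp")
  expect_equal(nrow(sub), 2)
  expect_true(all(is.finite(sub$auroc_mean)))
  # label permutation: groups share the outcome process, AUROCs similar
  expect_lt(abs(sub$auroc_mean[1] - sub$auroc_mean[2]), 0.15)

  pr$all_same <- "x"
  sub1 <- subgroup_performance(pr, "all_same")
  expect_equal(nrow(sub1), 1)
  expect_equal(sub1$auroc_mean, mean_time_varying_auroc(pr)$mean)

  pr$noev <- ifelse(pr$d == 1, "has", "none")
  subn <- subgroup_performance(pr, "noev")
  expect_true(is.na(subn$auroc_mean[subn$group == "none"]))
})

test_that("evaluation reports aggregate the pieces coherently", {
  rows <- two_rate_cohort(23, n = 400, horizon = 720)
  sp <- split_cohort(unique(rows$patient_id), seed = 9)
  f <- fit_hazard_forest(rows[rows$patient_id %in% sp$train, ],
                         features = c("xbin", "noise1"), n_trees = 50,
                         seed = 10)
  rep <- evaluate_model(f, rows[rows$patient_id %in% sp$test, ],
                        n_boot = 100, seed = 11)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$auroc_mean >= 0 && rep$auroc_mean <= 1)
  expect_equal(sum(rep$calibration$n),
               sum(rows$patient_id %in% sp$test))
  expect_true(rep$bootstrap$conf.low <= rep$bootstrap$conf.high)
  g <- glance(rep)
  expect_equal(g$auroc_mean, rep$auroc_mean)
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "eval_report.json"))
  expect_equal(js$auroc_mean, rep$auroc_mean, tolerance = 1e-9)
})
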