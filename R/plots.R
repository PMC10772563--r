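#' @export
autoplot.eval_report <- function(object, ...) {
  tab <- object$intervals |> filter(.data$valid)
  ggplot2::ggplot(tab, ggplot2::aes(x = (.data$k + 1) * 3, y = .data$auroc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2b6cb0") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_events),
                        colour = "#2b6cb0", alpha = 0.8) +
    ggplot2::scale_size_continuous(name = "events") +
    ggplot2::labs(x = "Follow-up (months)", y = "Time-specific AUROC",
                  title = sprintf("%s model: mean AUROC %.3f ± %.3f",
                                  object$model_type, object$auroc_mean,
                                  object$auroc_sd)) +
    ggplot2::coord_cartesian(ylim = c(0.3, 1)) +
    ggplot2::theme_minimal()
}

#' Time-varying AUROC comparison of several evaluation reports
#'
#' @param ... Named [evaluate_model()] reports (e.g. `dynamic = ...,
#'   static = ...`).
#' @return A ggplot object.
#' @export
plot_auroc_comparison <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  tab <- purrr::imap_dfr(reports, function(r, nm)
    r$intervals |> filter(.data$valid) |> mutate(model = nm))
  ggplot2::ggplot(tab, ggplot2::aes(x = (.data$k + 1) * 3, y = .data$auroc,
                                    colour = .data$model)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Follow-up (months)", y = "Time-specific AUROC",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Decile calibration plot
#'
#' @param calib Table from [calibration_deciles()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calib) {
  ggplot2::ggplot(calib, ggplot2::aes(x = .data$mean_predicted,
                                      y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "#2b6cb0") +
    ggplot2::geom_line(colour = "#2b6cb0") +
    ggplot2::labs(x = "Mean predicted 90-day risk",
                  y = "Observed event rate", size = "rows") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.latent_traversal <- function(object, ...) {
  tab <- tidy(object)
  pct_lab <- factor(seq_along(object$values),
                    labels = sprintf("value %.2f", object$values))
  tab$grid_lab <- pct_lab[tab$grid]
  if (!is.null(tab$lead)) {
    tab$lead <- factor(tab$lead, levels = object$leads)
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$lead_sample,
                                           y = .data$grid_lab,
                                           fill = .data$abs_diff)) +
      ggplot2::facet_wrap(~lead, nrow = 1)
  } else {
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$sample,
                                           y = .data$grid_lab,
                                           fill = .data$abs_diff))
  }
  p + ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|Δ|") +
    ggplot2::labs(x = "Template sample", y = NULL,
                  title = paste("Factor traversal of", object$dimension)) +
    ggplot2::theme_minimal()
}

#' Permutation importance bar chart
#'
#' @param imp Table from [permutation_importance()].
#' @param top_n Number of features shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(imp, top_n = 20) {
  tab <- imp |> head(top_n) |>
    mutate(feature = stats::reorder(.data$feature, .data$importance))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2b6cb0") +
    ggplot2::labs(x = "Mean AUROC drop after permutation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a beat template
#'
#' @param tpl A [beat_template()].
#' @return A ggplot object with one facet per lead.
#' @export
plot_template <- function(tpl) {
  ws <- window_samples(tpl$window, tpl$fs)
  t_rel <- seq(-ws[["pre"]], ws[["post"]] - 1L) / tpl$fs
  tab <- tibble(lead = factor(rep(tpl$leads, each = ncol(tpl$waveforms)),
                              levels = tpl$leads),
                t = rep(t_rel, nrow(tpl$waveforms)),
                value = as.vector(t(tpl$waveforms)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#2b6cb0") +
    ggplot2::facet_wrap(~lead, nrow = 2) +
    ggplot2::labs(x = "Time from R peak (s)",
                  y = if (tpl$normalized) "Normalised amplitude"
                  else "Amplitude (mV)") +
    ggplot2::theme_minimal()
}
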