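#' Carpet plot of band-filtered flow across vessels
#'
#' Vessels x time heatmap of the TGF band-filtered BFI, the standard visual
#' for oscillation presence and inter-vessel synchrony: synchronized vessels
#' produce vertical striations, heterogeneous phases a patchwork. Color
#' limits are symmetric about zero.
#'
#' @param filtered Long tibble with columns `vessel_id`, `t`, and the
#'   filtered value column `bfi_f` (see [bandpass_tgf()]).
#' @param window Seconds of record to show (default 600).
#' @return A ggplot object.
#' @export
plot_carpet <- function(filtered, window = 600) {
  stopifnot(all(c("vessel_id", "t", "bfi_f") %in% names(filtered)))
  d <- dplyr::filter(filtered, .data$t < window)
  lim <- max(abs(d$bfi_f), 1e-12)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t,
                                  y = factor(.data$vessel_id),
                                  fill = .data$bfi_f)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim),
                                  name = "Filtered BFI") +
    ggplot2::labs(x = "Time (s)", y = "Vessel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Add the TGF band-filtered signal to a cohort of series
#'
#' Convenience verb: groups by the available identifiers and appends a
#' `bfi_f` column with the [bandpass_tgf()] output.
#'
#' @param series Long series tibble (columns `t`, `bfi`, identifiers).
#' @inheritParams bandpass_tgf
#' @return The input with an extra `bfi_f` column.
#' @export
add_band_filtered <- function(series, band = c(0.015, 0.04), rate = 1) {
  keys <- intersect(c("animal_id", "vessel_id", "period"), names(series))
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(bfi_f = bandpass_tgf(.data$bfi, band, rate)) |>
    dplyr::ungroup()
}

#' Box plots of the three TGF metrics per period
#'
#' @param metrics Metrics tibble from [compute_metrics()] with both periods.
#' @return A ggplot object, one panel per metric.
#' @export
plot_metric_box <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              dplyr::any_of(c("bfi_mean", "sigma", "auc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value,
                                     fill = .data$period)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Metric value (a.u.)") +
    ggplot2::theme_minimal()
}

#' 3-D scatter of the metric triplet per vessel
#'
#' (BFI, Sigma, AUC) for every vessel, colored by period; separation of the
#' two clouds visualizes the drug effect across all three metrics at once.
#'
#' @param metrics Metrics tibble with both periods.
#' @return A lattice `cloud` object (print it to render).
#' @export
plot_metric_scatter3d <- function(metrics) {
  stopifnot(all(c("bfi_mean", "sigma", "auc", "period") %in% names(metrics)))
  lattice::cloud(auc ~ bfi_mean * sigma, data = metrics,
                 groups = metrics$period, auto.key = TRUE,
                 xlab = "BFI", ylab = "Sigma", zlab = "AUC")
}

#' Standardized centroid separation of the metric clouds
#'
#' Euclidean distance between the control and drug centroids in (BFI,
#' Sigma, AUC) space after standardizing each axis by its pooled SD; > 1
#' indicates clearly separated clusters, near 0 overlapping ones.
#'
#' @param metrics Metrics tibble with both periods.
#' @return A non-negative scalar.
#' @export
metric_separation <- function(metrics) {
  cols <- intersect(c("bfi_mean", "sigma", "auc"), names(metrics))
  stopifnot(length(cols) >= 1, "period" %in% names(metrics))
  z <- metrics
  for (cl in cols) {
    s <- sd(z[[cl]])
    z[[cl]] <- if (s > 0) z[[cl]] / s else z[[cl]] * 0
  }
  cent <- z |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  if (nrow(cent) != 2L) {
    abort("Metrics must contain exactly two periods.",
          class = "tgflsci_contract_error")
  }
  sqrt(sum((as.numeric(cent[1, cols]) - as.numeric(cent[2, cols]))^2))
}
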