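#' Mean blood flow index of a series
#'
#' @param series Flow-series tibble (column `bfi`) or numeric vector.
#' @return Arithmetic mean over the period.
#' @export
bfi_mean <- function(series) {
  x <- series_values(series)
  if (length(x) == 0L) {
    abort("Series is empty.", class = "tgflsci_contract_error")
  }
  mean(x)
}

#' Band-pass filter a flow series to the TGF band
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and backward
#' through [signal::filtfilt()]) on an odd-reflection-padded copy of the
#' series, so filter transients never touch the record. The response
#' contract: gain >= 0.95 at 0.0275 Hz (mid-band) and <= 0.05 at 0.1 Hz
#' (myogenic band) and at DC.
#'
#' @param series Flow-series tibble or numeric vector at 1 Hz.
#' @param band Pass band in Hz (default 0.015--0.04, the TGF band).
#' @param rate Sampling rate, Hz.
#' @return Numeric vector, the filtered (zero-mean) series.
#' @export
bandpass_tgf <- function(series, band = c(0.015, 0.04), rate = 1) {
  x <- series_values(series)
  n <- length(x)
  pad <- ceiling(3 * rate / band[1])      # three longest-period lengths
  if (n <= pad / 3 + 1) {
    abort(sprintf(
      "Series too short to pad for the %g Hz band (needs > %d samples).",
      band[1], ceiling(rate / band[1]) + 1),
      class = "tgflsci_contract_error")
  }
  pad <- min(pad, n - 1L)
  if (n < 300 * rate) {
    warn("Series shorter than 300 s; band-pass estimates will be unstable.")
  }
  bf <- signal::butter(4, 2 * band / rate, type = "pass")
  # the pass band excludes DC, so remove the mean up front: this zeroes
  # constant series exactly and shrinks start-up transients
  x <- x - mean(x)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Sigma metric: TGF oscillation amplitude
#'
#' Sample standard deviation of the band-filtered series; for a pure
#' in-band sinusoid of amplitude A this converges to A/sqrt(2).
#'
#' @param filtered Numeric vector from [bandpass_tgf()].
#' @return Non-negative scalar.
#' @export
sigma_metric <- function(filtered) {
  if (length(filtered) < 2L) return(0)
  sd(filtered)
}

#' AUC metric: baseline-corrected TGF band power
#'
#' Trapezoidal integral of the power spectrum over the TGF band minus a
#' horizontal baseline at the median power of the 0.04--0.05 Hz samples
#' (area `median * band width`). Negative values are allowed: they indicate
#' band power below the local noise floor. Frequencies reported missing by
#' [time_avg_spectrum()] (no edge-free cells, as happens for short records)
#' are omitted from both the integral and the median.
#'
#' @param ps A `power_spectrum` tibble (`f`, `power`) covering both bands.
#' @param band TGF band, Hz.
#' @param baseline_band Baseline band, Hz.
#' @return Scalar in power x Hz units.
#' @examples
#' f <- seq(0.01, 0.06, by = 0.001)
#' auc_metric(tibble::tibble(f = f, power = ifelse(f <= 0.04, 2, 1)))
#' @export
auc_metric <- function(ps, band = c(0.015, 0.04),
                       baseline_band = c(0.04, 0.05)) {
  f <- ps$f; pw <- ps$power
  if (min(f) > band[1] || max(f) < baseline_band[2]) {
    abort("Spectrum does not cover the TGF and baseline bands.",
          class = "tgflsci_contract_error")
  }
  a_band <- band_trapz(f, pw, band[1], band[2])
  m <- stats::median(pw[f >= baseline_band[1] & f <= baseline_band[2]],
                     na.rm = TRUE)
  a_band - m * (band[2] - band[1])
}

#' Compute the three TGF metrics for every vessel and period
#'
#' For each `(animal_id, vessel_id, period)` group: mean BFI, Sigma (SD of
#' the TGF band-filtered series), and AUC (baseline-corrected superlet band
#' power). This is the per-vessel unit of statistical comparison between
#' control and drug periods.
#'
#' @param series Long tibble with columns `vessel_id`, `t`, `bfi` and
#'   optionally `animal_id`, `period`.
#' @param band,baseline_band TGF and baseline bands, Hz.
#' @param superlet A [superlet_params()] for the spectra; the default grid
#'   spans 0.01--0.06 Hz — enough to cover both bands (with margin for the
#'   band edges) while keeping cohort-scale computation cheap.
#' @param rate Sampling rate, Hz.
#' @return A tibble, one row per group, with columns `bfi_mean`, `sigma`,
#'   `auc` plus the grouping identifiers.
#' @export
compute_metrics <- function(series, band = c(0.015, 0.04),
                            baseline_band = c(0.04, 0.05),
                            superlet = superlet_params(f_min = 0.01, f_max = 0.06),
                            rate = 1) {
  stopifnot(is.data.frame(series), "bfi" %in% names(series))
  keys <- intersect(c("animal_id", "vessel_id", "period"), names(series))
  if (length(keys) == 0L) {
    series$vessel_id <- 1L
    keys <- "vessel_id"
  }
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      bfi_mean = bfi_mean(.data$bfi),
      sigma = sigma_metric(bandpass_tgf(.data$bfi, band, rate)),
      auc = auc_metric(
        time_avg_spectrum(superlet_spectrogram(.data$bfi, superlet, rate)),
        band, baseline_band),
      .groups = "drop")
}
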