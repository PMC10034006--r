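#' Superlet analysis parameters
#'
#' The superlet estimates time-frequency power as the geometric mean of a
#' set of Morlet wavelets sharing a center frequency but with increasing
#' cycle counts (`c1`, `2*c1`, ..., `o*c1`; the multiplicative scheme).
#' Short wavelets give temporal precision, long wavelets frequency
#' precision; their geometric mean retains both, which is what makes slow,
#' drifting TGF oscillations resolvable in 30-min records.
#'
#' The order grows linearly across the grid from `order_min` at `f_min` to
#' `order_max` at `f_max` (adaptive superlet). Defaults suit 1800-sample,
#' 1 Hz flow records: a 0.005--0.25 Hz grid in 0.001 Hz steps (246 bins).
#'
#' @param f_min,f_max Frequency grid limits, Hz.
#' @param f_step Grid step, Hz.
#' @param c1 Base cycle count (>= 1).
#' @param order_min,order_max Superlet order range (>= 1).
#' @param k_sd Cycles are counted over `k_sd` standard deviations of the
#'   Gaussian envelope: the envelope SD at frequency f with c cycles is
#'   `c / (k_sd * f)` seconds.
#' @param coi_sd Cone-of-influence half-width in envelope SDs of the longest
#'   wavelet; cells closer than this to either record edge are flagged.
#' @return A list of class `superlet_params`.
#' @export
superlet_params <- function(f_min = 0.005, f_max = 0.25, f_step = 0.001,
                            c1 = 3, order_min = 1, order_max = 10,
                            k_sd = 5, coi_sd = 2) {
  check_number(f_min, "f_min", lower = 1e-9)
  check_number(f_max, "f_max", lower = f_min)
  check_number(f_step, "f_step", lower = 1e-12)
  check_count(c1, "c1", lower = 1L)
  check_count(order_min, "order_min", lower = 1L)
  check_count(order_max, "order_max", lower = order_min)
  check_number(k_sd, "k_sd", lower = 1e-9)
  check_number(coi_sd, "coi_sd", lower = 0)
  structure(list(f_min = f_min, f_max = f_max, f_step = f_step, c1 = c1,
                 order_min = order_min, order_max = order_max,
                 k_sd = k_sd, coi_sd = coi_sd, mode = "multiplicative"),
            class = "superlet_params")
}

# -- internal Morlet machinery ----------------------------------------------

# Unit-energy complex Morlet sampled at `rate`; envelope SD b = cycles/(k_sd f).
morlet_kernel <- function(f, cycles, rate, k_sd = 5) {
  b <- cycles / (k_sd * f)
  half <- ceiling(4 * b * rate)
  tt <- (-half:half) / rate
  psi <- exp(-tt^2 / (2 * b^2)) * exp(2i * pi * f * tt)
  psi / sqrt(sum(Mod(psi)^2) / rate)
}

# FFT caches, keyed by kernel/pad geometry, so a cohort of equally sized
# series reuses every wavelet spectrum.
the_kernel_cache <- new.env(parent = emptyenv())

kernel_fft <- function(f, cycles, rate, k_sd, npad) {
  key <- paste(f, cycles, rate, k_sd, npad, sep = "|")
  hit <- the_kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  psi <- morlet_kernel(f, cycles, rate, k_sd)
  P <- fft(c(psi, rep(0, npad - length(psi))))
  res <- list(P = P, half = (length(psi) - 1L) %/% 2L)
  the_kernel_cache[[key]] <- res
  res
}

# Magnitude of the linear ("same"-aligned) convolution of x with the Morlet
# at (f, cycles). Accepts a precomputed padded FFT of x.
morlet_conv_mag <- function(x, f, cycles, rate, k_sd = 5,
                            xfft = NULL, npad = NULL) {
  n <- length(x)
  b <- cycles / (k_sd * f)
  m <- 2L * ceiling(4 * b * rate) + 1L
  need <- nextn(n + m - 1L)
  if (is.null(xfft) || is.null(npad) || npad < need) {
    npad <- need
    xfft <- fft(c(x, rep(0, npad - n)))
  }
  kf <- kernel_fft(f, cycles, rate, k_sd, npad)
  y <- fft(xfft * kf$P, inverse = TRUE) / npad
  Mod(y[(kf$half + 1L):(kf$half + n)])
}

series_values <- function(series) {
  if (is.data.frame(series)) series$bfi else as.numeric(series)
}

#' Morlet wavelet response of a flow series
#'
#' Magnitude of the convolution of the (internally demeaned) series with a
#' unit-energy complex Morlet wavelet of center frequency `f` and `cycles`
#' cycles. Zero-padded edges (within `coi_sd` envelope SDs of the record
#' ends) are flagged in attribute `"edge"`.
#'
#' @param series A flow-series tibble with column `bfi`, or a numeric vector.
#' @param f Center frequency, Hz (must be below Nyquist).
#' @param cycles Number of cycles (>= 1).
#' @param rate Sampling rate, Hz (default 1).
#' @param k_sd,coi_sd See [superlet_params()].
#' @return Numeric vector of response magnitudes, with logical attribute
#'   `"edge"`.
#' @export
morlet_response <- function(series, f, cycles, rate = 1, k_sd = 5,
                            coi_sd = 2) {
  x <- series_values(series)
  if (f >= rate / 2) {
    abort("`f` must be below the Nyquist frequency.",
          class = "tgflsci_contract_error")
  }
  check_number(cycles, "cycles", lower = 1)
  x <- x - mean(x)
  r <- morlet_conv_mag(x, f, cycles, rate, k_sd)
  b <- cycles / (k_sd * f)
  edge_n <- ceiling(coi_sd * b * rate)
  n <- length(x)
  edge <- seq_len(n) <= edge_n | seq_len(n) > n - edge_n
  attr(r, "edge") <- edge
  r
}

# Adaptive order at frequency f (round-half-up for platform determinism).
superlet_order <- function(f, p) {
  if (p$f_max == p$f_min) return(p$order_min)
  o <- p$order_min + (p$order_max - p$order_min) *
    (f - p$f_min) / (p$f_max - p$f_min)
  as.integer(floor(o + 0.5))
}

#' Superlet time-frequency spectrogram
#'
#' For each grid frequency f with order o(f), power is the squared geometric
#' mean of the magnitudes of `o` Morlet responses with cycle counts
#' `c1, 2 c1, ..., o c1`:
#' \deqn{P(t, f) = \Big[\prod_{i=1}^{o} R_i(t, f)\Big]^{2/o}.}
#' Order 1 reduces exactly to base Morlet wavelet power. The series is
#' demeaned (optionally linearly detrended) before the transform.
#'
#' @param series Flow-series tibble (column `bfi`) or numeric vector.
#' @param params A [superlet_params()].
#' @param rate Sampling rate, Hz (default 1).
#' @param detrend Remove a linear trend instead of just the mean.
#' @return A `superlet_spectrogram`: list with `power` (time x frequency),
#'   `t`, `f`, `coi` (logical time x frequency, `TRUE` = edge-affected), and
#'   the parameters.
#' @examples
#' ser <- gen_flow_series(flow_series_params(duration_s = 600, noise_sd = 0,
#'   myo_amp = 0), seed = 1)
#' sg <- superlet_spectrogram(ser, superlet_params(f_max = 0.06))
#' sp <- time_avg_spectrum(sg)
#' sp$f[which.max(sp$power)]
#' @export
superlet_spectrogram <- function(series, params = superlet_params(),
                                 rate = 1, detrend = FALSE) {
  stopifnot(inherits(params, "superlet_params"))
  x <- series_values(series)
  n <- length(x)
  if (params$f_max >= rate / 2) {
    abort("`f_max` must be below the Nyquist frequency.",
          class = "tgflsci_contract_error")
  }
  if (n < 10 * rate / params$f_min) {
    warn(paste0("Series shorter than 10 cycles of `f_min`; ",
                "low-frequency estimates will be edge-dominated."))
  }
  if (detrend) {
    tt <- seq_len(n)
    x <- stats::residuals(stats::lm(x ~ tt))
  } else {
    x <- x - mean(x)
  }
  freqs <- seq(params$f_min, params$f_max, by = params$f_step)
  # shared zero-padded FFT sized for the longest kernel on the grid
  o_all <- vapply(freqs, superlet_order, integer(1), p = params)
  b_max_all <- (o_all * params$c1) / (params$k_sd * freqs)
  m_max <- 2L * ceiling(4 * max(b_max_all) * rate) + 1L
  npad <- nextn(n + m_max - 1L)
  xfft <- fft(c(x, rep(0, npad - n)))

  power <- matrix(0, n, length(freqs))
  coi <- matrix(FALSE, n, length(freqs))
  idx <- seq_len(n)
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    o <- o_all[j]
    logsum <- numeric(n)
    for (i in seq_len(o)) {
      r <- morlet_conv_mag(x, f, i * params$c1, rate, params$k_sd,
                           xfft = xfft, npad = npad)
      logsum <- logsum + log(r)
    }
    power[, j] <- exp((2 / o) * logsum)
    edge_n <- ceiling(params$coi_sd * b_max_all[j] * rate)
    coi[, j] <- idx <= edge_n | idx > n - edge_n
  }
  structure(list(power = power, t = (idx - 1) / rate, f = freqs, coi = coi,
                 params = params, rate = rate),
            class = "superlet_spectrogram")
}

#' @export
print.superlet_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<superlet_spectrogram> %d time points x %d frequencies (%g-%g Hz)\n",
    length(x$t), length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

#' @describeIn superlet_spectrogram Long-format tibble (`t`, `f`, `power`,
#'   `edge`) of a spectrogram.
#' @param x A `superlet_spectrogram`.
#' @param ... Unused.
#' @method tidy superlet_spectrogram
#' @export
tidy.superlet_spectrogram <- function(x, ...) {
  tibble(t = rep(x$t, times = length(x$f)),
         f = rep(x$f, each = length(x$t)),
         power = as.vector(x$power),
         edge = as.vector(x$coi))
}

#' Time-averaged power spectrum
#'
#' Mean spectrogram power over time per frequency, excluding edge-flagged
#' (cone-of-influence) cells. Frequencies whose cells are all flagged are
#' reported as `NA` with a warning.
#'
#' @param sg A `superlet_spectrogram`.
#' @return A tibble (`f`, `power`) of class `power_spectrum`.
#' @export
time_avg_spectrum <- function(sg) {
  stopifnot(inherits(sg, "superlet_spectrogram"))
  p <- sg$power
  p[sg$coi] <- NA_real_
  pw <- colMeans(p, na.rm = TRUE)
  missing <- colSums(!sg$coi) == 0
  pw[missing] <- NA_real_
  if (any(missing)) {
    warn(sprintf(
      "No edge-free cells at %d frequencies (e.g. %g Hz); reported as NA.",
      sum(missing), sg$f[which(missing)[1]]))
  }
  structure(tibble(f = sg$f, power = pw),
            class = c("power_spectrum", class(tibble())))
}

#' Classify the TGF oscillation pattern of a power spectrum
#'
#' Counts local maxima inside the TGF band whose power exceeds
#' `prominence_factor` times the median power in a neighboring baseline
#' band: 0 peaks mean no detectable TGF oscillation, 1 a single stable
#' frequency, and 2+ a drifting/multi-frequency oscillation.
#'
#' @param ps A `power_spectrum` (tibble with `f`, `power`).
#' @param band TGF band, Hz.
#' @param baseline_band Reference band for the detection floor, Hz.
#' @param prominence_factor Peak threshold as a multiple of the baseline
#'   median power.
#' @return `"none"`, `"single"`, or `"multiple"`.
#' @export
classify_tgf_pattern <- function(ps, band = c(0.015, 0.04),
                                 baseline_band = c(0.04, 0.05),
                                 prominence_factor = 3) {
  f <- ps$f; pw <- ps$power
  if (min(f) > band[1] || max(f) < baseline_band[2]) {
    abort("Spectrum does not cover the TGF and baseline bands.",
          class = "tgflsci_contract_error")
  }
  base <- pw[f >= baseline_band[1] & f <= baseline_band[2]]
  base_med <- stats::median(base, na.rm = TRUE)
  in_band <- which(f >= band[1] & f <= band[2])
  n_peaks <- 0L
  for (i in in_band) {
    if (is.na(pw[i])) next
    left <- if (i > 1L) pw[i - 1L] else -Inf
    right <- if (i < length(pw)) pw[i + 1L] else -Inf
    is_max <- !is.na(left) && !is.na(right) && pw[i] > left && pw[i] > right
    if (is_max && pw[i] > prominence_factor * base_med && pw[i] > 0) {
      n_peaks <- n_peaks + 1L
    }
  }
  if (n_peaks == 0L) "none" else if (n_peaks == 1L) "single" else "multiple"
}
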