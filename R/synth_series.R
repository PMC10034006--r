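#' Parameters for a synthetic blood-flow-index time series
#'
#' Bundles the signal model for a single microvessel's 1 Hz blood-flow-index
#' (BFI) record: a constant mean flow, a tubuloglomerular-feedback (TGF)
#' oscillation in the 0.015--0.04 Hz band whose instantaneous frequency may
#' drift linearly (a slow chirp), a faster myogenic component near 0.1 Hz,
#' and additive Gaussian noise.
#'
#' @param duration_s Record length in seconds (default 1800, i.e. a 30-min
#'   observation period).
#' @param rate_hz Sampling rate in Hz (default 1).
#' @param mean_bfi Mean flow level, arbitrary BFI units.
#' @param tgf_freq_hz TGF oscillation frequency at t = 0, Hz. Physiological
#'   values fall in 0.015--0.04 Hz.
#' @param tgf_amp TGF oscillation amplitude, BFI units (>= 0).
#' @param tgf_drift_hz_per_s Linear drift of the instantaneous TGF frequency,
#'   Hz per second (0 for a stable oscillation).
#' @param myo_freq_hz Myogenic component frequency, Hz (~0.1).
#' @param myo_amp Myogenic component amplitude, BFI units (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise, BFI units.
#' @param phase_rad Initial phase of the TGF component, radians.
#'
#' @return A list of class `flow_series_params`.
#' @seealso [gen_flow_series()]
#' @export
flow_series_params <- function(duration_s = 1800, rate_hz = 1, mean_bfi = 60,
                               tgf_freq_hz = 0.03, tgf_amp = 5,
                               tgf_drift_hz_per_s = 0,
                               myo_freq_hz = 0.1, myo_amp = 1.5,
                               noise_sd = 2, phase_rad = 0) {
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(rate_hz, "rate_hz", lower = 1e-9)
  check_number(mean_bfi, "mean_bfi")
  check_number(tgf_amp, "tgf_amp", lower = 0)
  check_number(myo_amp, "myo_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(tgf_freq_hz, "tgf_freq_hz", lower = 0, allow_zero = FALSE)
  check_number(myo_freq_hz, "myo_freq_hz", lower = 0)
  check_number(tgf_drift_hz_per_s, "tgf_drift_hz_per_s")
  check_number(phase_rad, "phase_rad")
  f_end <- tgf_freq_hz + tgf_drift_hz_per_s * duration_s
  if (f_end <= 0 || f_end >= rate_hz / 2 || tgf_freq_hz >= rate_hz / 2) {
    abort("`tgf_freq_hz` (+ drift) must stay within (0, rate_hz/2) over the record.",
          class = "tgflsci_parameter_error")
  }
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz, mean_bfi = mean_bfi,
         tgf_freq_hz = tgf_freq_hz, tgf_amp = tgf_amp,
         tgf_drift_hz_per_s = tgf_drift_hz_per_s, myo_freq_hz = myo_freq_hz,
         myo_amp = myo_amp, noise_sd = noise_sd, phase_rad = phase_rad),
    class = "flow_series_params"
  )
}

#' Generate a synthetic blood-flow-index time series
#'
#' Simulates a per-vessel BFI record
#' \deqn{y(t) = \mu + A_{tgf} \sin(2\pi \int_0^t f(u)\,du + \phi)
#'   + A_{myo} \sin(2\pi f_{myo} t) + \epsilon(t),}
#' with \eqn{f(u) = f_{tgf} + d\,u} (linear chirp) and i.i.d. Gaussian
#' \eqn{\epsilon}. The same `params` and `seed` always reproduce the same
#' series bit for bit.
#'
#' @param params A [flow_series_params()] object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `t` (seconds) and `bfi`, carrying the
#'   generator parameters in attribute `"truth"`.
#' @examples
#' ser <- gen_flow_series(flow_series_params(duration_s = 600, noise_sd = 0))
#' range(ser$bfi)
#' @export
gen_flow_series <- function(params = flow_series_params(), seed = NULL) {
  stopifnot(inherits(params, "flow_series_params"))
  n <- floor(params$duration_s * params$rate_hz)
  t <- seq_len(n) / params$rate_hz - 1 / params$rate_hz
  # phase of the chirp: 2*pi * (f0 t + d t^2 / 2)
  ph <- 2 * pi * (params$tgf_freq_hz * t +
                    params$tgf_drift_hz_per_s * t^2 / 2) + params$phase_rad
  bfi <- params$mean_bfi +
    params$tgf_amp * sin(ph) +
    params$myo_amp * sin(2 * pi * params$myo_freq_hz * t)
  if (params$noise_sd > 0) {
    bfi <- bfi + with_seed_or_current(seed, rnorm(n, sd = params$noise_sd))
  }
  out <- tibble(t = t, bfi = bfi)
  attr(out, "truth") <- c(unclass(params), list(seed = seed))
  out
}

#' Design of a synthetic two-period cohort
#'
#' Describes a multi-animal experiment with a 30-min control period and a
#' 30-min drug period per vessel. Presets mirror the qualitative pharmacology:
#' furosemide (NKCC2 inhibition at the macula densa) abolishes TGF
#' oscillations and raises mean flow by 11.3%; phlorizin (SGLT1/2 inhibition)
#' attenuates the oscillation and lowers mean flow by 6.42%.
#'
#' @param n_animals Number of animals (>= 1).
#' @param vessels_per_animal Segmented star vessels per animal (>= 1).
#' @param drug One of `"furosemide"`, `"phlorizin"`, `"none"`. Presets fill
#'   `mean_shift_frac` and `amp_scale` unless both are supplied.
#' @param mean_shift_frac Signed relative change of mean BFI in the drug
#'   period (e.g. `+0.113`).
#' @param amp_scale Multiplier in \[0, 1\] applied to the TGF amplitude in the
#'   drug period (0 abolishes the oscillation).
#' @param animal_sd Between-animal spread (random intercept SD) of mean BFI.
#' @param base_params [flow_series_params()] template for every vessel.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_animals = 5, vessels_per_animal = 60,
                          drug = c("furosemide", "phlorizin", "none"),
                          mean_shift_frac = NULL, amp_scale = NULL,
                          animal_sd = 5,
                          base_params = flow_series_params()) {
  drug <- match.arg(drug)
  preset <- switch(drug,
    furosemide = list(mean_shift_frac = +0.113, amp_scale = 0),
    phlorizin  = list(mean_shift_frac = -0.0642, amp_scale = 0.4),
    none       = list(mean_shift_frac = 0, amp_scale = 1)
  )
  mean_shift_frac <- mean_shift_frac %||% preset$mean_shift_frac
  amp_scale <- amp_scale %||% preset$amp_scale
  check_count(n_animals, "n_animals", lower = 1L)
  check_count(vessels_per_animal, "vessels_per_animal", lower = 1L)
  check_number(mean_shift_frac, "mean_shift_frac", lower = -1)
  check_number(amp_scale, "amp_scale", lower = 0, upper = 1)
  check_number(animal_sd, "animal_sd", lower = 0)
  stopifnot(inherits(base_params, "flow_series_params"))
  structure(
    list(n_animals = as.integer(n_animals),
         vessels_per_animal = as.integer(vessels_per_animal),
         drug = drug, mean_shift_frac = mean_shift_frac,
         amp_scale = amp_scale, animal_sd = animal_sd,
         base_params = base_params),
    class = "cohort_design"
  )
}

#' Generate a synthetic control/drug cohort of vessel flow series
#'
#' Per animal, a random intercept (SD `animal_sd`) shifts the mean BFI of all
#' its vessels. Per vessel, the TGF amplitude is scaled by a uniform
#' multiplier in \[0.2, 1\] (some vessels oscillate strongly, some weakly),
#' and the TGF frequency is drawn uniformly from 0.018--0.033 Hz with a
#' random phase. The drug period reuses each vessel's parameters with
#' `mean_bfi * (1 + mean_shift_frac)` and `tgf_amp * amp_scale` and a fresh
#' noise realization.
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed for the whole cohort.
#' @return A tibble with columns `animal_id`, `vessel_id`, `period`
#'   (`"control"`/`"drug"`), `t`, `bfi`; per-vessel generator parameters in
#'   attribute `"truth"`.
#' @examples
#' coh <- gen_cohort(cohort_design(n_animals = 2, vessels_per_animal = 3,
#'   base_params = flow_series_params(duration_s = 300)), seed = 1)
#' dplyr::count(coh, animal_id, period)
#' @export
gen_cohort <- function(design = cohort_design(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  bp <- design$base_params
  with_seed_or_current(seed, {
    intercepts <- rnorm(design$n_animals, sd = design$animal_sd)
    rows <- list()
    truth <- list()
    for (a in seq_len(design$n_animals)) {
      for (v in seq_len(design$vessels_per_animal)) {
        amp_mult <- runif(1, 0.2, 1)
        f_tgf <- runif(1, 0.018, 0.033)
        phase <- runif(1, 0, 2 * pi)
        mean_ctl <- bp$mean_bfi + intercepts[a]
        p_ctl <- flow_series_params(
          duration_s = bp$duration_s, rate_hz = bp$rate_hz,
          mean_bfi = mean_ctl, tgf_freq_hz = f_tgf,
          tgf_amp = bp$tgf_amp * amp_mult,
          tgf_drift_hz_per_s = bp$tgf_drift_hz_per_s,
          myo_freq_hz = bp$myo_freq_hz, myo_amp = bp$myo_amp,
          noise_sd = bp$noise_sd, phase_rad = phase)
        p_drug <- p_ctl
        p_drug$mean_bfi <- mean_ctl * (1 + design$mean_shift_frac)
        p_drug$tgf_amp <- p_ctl$tgf_amp * design$amp_scale
        s_ctl <- gen_flow_series(p_ctl)
        s_drug <- gen_flow_series(p_drug)
        key <- tibble(animal_id = a, vessel_id = (a - 1L) *
                        design$vessels_per_animal + v)
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          dplyr::mutate(s_ctl, period = "control"),
          dplyr::mutate(s_drug, period = "drug")
        ) |> dplyr::mutate(animal_id = key$animal_id,
                           vessel_id = key$vessel_id)
        truth[[length(truth) + 1L]] <- tibble(
          animal_id = key$animal_id, vessel_id = key$vessel_id,
          animal_intercept = intercepts[a], amp_mult = amp_mult,
          tgf_freq_hz = f_tgf, phase_rad = phase,
          mean_bfi_control = mean_ctl,
          mean_bfi_drug = p_drug$mean_bfi,
          tgf_amp_control = p_ctl$tgf_amp,
          tgf_amp_drug = p_drug$tgf_amp)
      }
    }
    out <- dplyr::bind_rows(rows) |>
      dplyr::select("animal_id", "vessel_id", "period", "t", "bfi")
    attr(out, "truth") <- dplyr::bind_rows(truth)
    attr(out, "design") <- unclass(design)
    out
  })
}
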