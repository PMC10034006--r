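tone <- function(f0, n = 600, amp = 1, phase = 0) {
  amp * sin(2 * pi * f0 * (0:(n - 1)) + phase)
}

test_that("Morlet response matches a direct time-domain convolution", {
  set.seed(21)
  x <- rnorm(80)
  r <- morlet_response(x, f = 0.05, cycles = 3)
  oracle <- direct_morlet_mag(x - mean(x), 0.05, 3)
  expect_equal(as.vector(r), oracle, tolerance = 1e-10)
})

test_that("Morlet response is frequency selective and phase invariant", {
  expect_true(all(morlet_response(rep(0, 200), 0.05, 3) == 0))

  x <- tone(0.05, 1200)
  mid <- 400:800
  r_on <- mean(morlet_response(x, 0.05, 3)[mid])
  r_off <- mean(morlet_response(x, 0.10, 3)[mid])
  expect_gt(r_on / r_off, 5)

  r_ph <- mean(morlet_response(tone(0.05, 1200, phase = 1.1), 0.05, 3)[mid])
  expect_equal(r_ph / r_on, 1, tolerance = 0.01)

  expect_error(morlet_response(x, f = 0.6, cycles = 3),
               class = "tgflsci_contract_error")
})

test_that("order-1 superlets equal base Morlet wavelet power bin for bin", {
  ser <- gen_flow_series(flow_series_params(duration_s = 900), seed = 22)
  p1 <- superlet_params(f_min = 0.01, f_max = 0.1, f_step = 0.005,
                        order_min = 1, order_max = 1)
  sg <- suppressWarnings(superlet_spectrogram(ser, p1))
  for (j in c(1, 5, 10, length(sg$f))) {
    mr <- morlet_response(ser, sg$f[j], cycles = 3)
    expect_lt(max(abs(sg$power[, j] - mr^2)) / max(mr^2), 1e-9)
  }
})

test_that("superlet power sits between the min and max wavelet powers", {
  ser <- gen_flow_series(flow_series_params(duration_s = 900,
                                            tgf_drift_hz_per_s = 5e-6),
                         seed = 23)
  p <- superlet_params(f_min = 0.01, f_max = 0.06, f_step = 0.005)
  sg <- suppressWarnings(superlet_spectrogram(ser, p))
  x <- ser$bfi - mean(ser$bfi)
  for (j in c(2, 5, 9)) {
    f <- sg$f[j]
    o <- tgflsci:::superlet_order(f, p)
    mags <- sapply(seq_len(o), function(i) {
      as.vector(morlet_response(x, f, cycles = 3 * i))
    })
    lo <- apply(mags, 1, min)^2
    hi <- apply(mags, 1, max)^2
    expect_true(all(sg$power[, j] >= lo - 1e-12))
    expect_true(all(sg$power[, j] <= hi + 1e-12))
  }
})

test_that("zero input gives an all-zero spectrogram", {
  sg <- suppressWarnings(
    superlet_spectrogram(rep(0, 400), superlet_params(f_min = 0.02)))
  expect_true(all(sg$power == 0))
})

test_that("scaling the series scales power by the square", {
  ser <- gen_flow_series(flow_series_params(duration_s = 600), seed = 24)
  p <- superlet_params(f_min = 0.02, f_max = 0.06, f_step = 0.01)
  sg1 <- suppressWarnings(superlet_spectrogram(ser$bfi, p))
  sg2 <- suppressWarnings(superlet_spectrogram(ser$bfi * 3, p))
  expect_equal(sg2$power, 9 * sg1$power, tolerance = 1e-12)
})

test_that("time-averaged spectra localize band tones to one grid step", {
  for (f0 in seq(0.015, 0.04, by = 0.005)) {
    ser <- gen_flow_series(flow_series_params(tgf_freq_hz = f0, tgf_amp = 5,
                                              myo_amp = 0, noise_sd = 0))
    sp <- quiet_spectrum(ser)
    expect_lt(abs(sp$f[which.max(sp$power)] - f0), 0.001 + 1e-9)
  }
})

test_that("two-epoch signals produce two local band maxima", {
  t1 <- 0:899; t2 <- 900:1799
  x <- c(5 * sin(2 * pi * 0.02 * t1), 5 * sin(2 * pi * 0.035 * t2))
  sp <- quiet_spectrum(x)
  band <- which(sp$f >= 0.015 & sp$f <= 0.04)
  peaks <- sum(diff(sign(diff(sp$power[band]))) == -2)
  expect_gte(peaks, 2)
})

test_that("a slow chirp concentrates spectral mass in its sweep range", {
  # 0.02 -> 0.025 Hz across the record; resolving a 5 mHz sweep needs high
  # effective cycle counts, so a fixed high-order superlet is used
  ser <- gen_flow_series(flow_series_params(
    tgf_freq_hz = 0.02, tgf_drift_hz_per_s = 0.005 / 1800,
    tgf_amp = 5, myo_amp = 0, noise_sd = 0))
  p <- superlet_params(f_min = 0.01, f_max = 0.06, c1 = 8,
                       order_min = 5, order_max = 5)
  sp <- quiet_spectrum(ser, p)
  total <- sum(sp$power, na.rm = TRUE)
  inside <- sum(sp$power[sp$f >= 0.02 & sp$f <= 0.025], na.rm = TRUE)
  expect_lt(1 - inside / total, 0.10)
})

test_that("time averaging excludes cone-of-influence cells", {
  sg <- suppressWarnings(
    superlet_spectrogram(tone(0.03, 600), superlet_params(f_min = 0.02,
                                                          f_max = 0.06)))
  expect_true(any(sg$coi))
  sp <- time_avg_spectrum(sg)
  j <- which.min(abs(sg$f - 0.03))
  manual <- mean(sg$power[!sg$coi[, j], j])
  expect_equal(sp$power[j], manual)

  # a frequency whose cells are all edge-affected is reported missing
  short <- suppressWarnings(
    superlet_spectrogram(tone(0.03, 120), superlet_params(f_min = 0.005,
                                                          f_max = 0.06)))
  expect_warning(spm <- time_avg_spectrum(short), "NA")
  expect_true(anyNA(spm$power))
})

test_that("TGF pattern taxonomy separates single, absent, and multiple peaks", {
  n_none <- 0; n_single <- 0; n_multi <- 0
  for (s in 1:20) {
    wn <- gen_flow_series(flow_series_params(tgf_amp = 0, myo_amp = 0,
                                             noise_sd = 1), seed = 200 + s)
    if (classify_tgf_pattern(quiet_spectrum(wn)) == "none") {
      n_none <- n_none + 1
    }
    tn <- gen_flow_series(flow_series_params(tgf_freq_hz = 0.03,
                                             tgf_amp = 3.2, myo_amp = 0,
                                             noise_sd = 1), seed = 400 + s)
    if (classify_tgf_pattern(quiet_spectrum(tn)) == "single") {
      n_single <- n_single + 1
    }
    two <- gen_flow_series(flow_series_params(tgf_freq_hz = 0.02,
                                              tgf_amp = 3, myo_amp = 0,
                                              noise_sd = 0.5),
                           seed = 600 + s)
    two$bfi <- two$bfi + 3 * sin(2 * pi * 0.035 * two$t + s)
    if (classify_tgf_pattern(quiet_spectrum(two)) == "multiple") {
      n_multi <- n_multi + 1
    }
  }
  expect_gte(n_none, 18)
  expect_gte(n_single, 18)
  expect_gte(n_multi, 18)
})

test_that("band coverage is checked before classification", {
  sp <- tibble::tibble(f = seq(0.02, 0.03, 0.001), power = 1)
  expect_error(classify_tgf_pattern(sp), class = "tgflsci_contract_error")
})
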