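test_that("flow series follows its closed-form signal model", {
  # all components off -> constant series
  flat <- gen_flow_series(flow_series_params(duration_s = 100, mean_bfi = 60,
                                             tgf_amp = 0, myo_amp = 0,
                                             noise_sd = 0))
  expect_equal(flat$bfi, rep(60, 100))
  expect_equal(flat$t, 0:99)

  # pure 0.03 Hz sinusoid of amplitude 5: peak-to-peak 10, zero-crossing
  # spacing of the demeaned signal = half period = 16.7 s
  ser <- gen_flow_series(flow_series_params(duration_s = 1800, mean_bfi = 60,
                                            tgf_freq_hz = 0.03, tgf_amp = 5,
                                            myo_amp = 0, noise_sd = 0))
  expect_equal(max(ser$bfi) - min(ser$bfi), 10, tolerance = 0.01)
  d <- ser$bfi - 60
  crossings <- which(diff(sign(d)) != 0)
  expect_equal(mean(diff(crossings)), 1 / 0.03 / 2, tolerance = 0.05)
})

test_that("flow series generation is deterministic given a seed", {
  p <- flow_series_params(duration_s = 300)
  expect_identical(gen_flow_series(p, seed = 5), gen_flow_series(p, seed = 5))
  s1 <- gen_flow_series(p, seed = 5)
  s2 <- gen_flow_series(p, seed = 6)
  expect_false(identical(s1$bfi, s2$bfi))
})

test_that("noiseless series put their DFT peak at the TGF frequency", {
  for (f0 in c(0.018, 0.025, 0.033)) {
    ser <- gen_flow_series(flow_series_params(duration_s = 1000,
                                              tgf_freq_hz = f0,
                                              tgf_amp = 5, myo_amp = 0,
                                              noise_sd = 0))
    spec <- Mod(fft(ser$bfi - mean(ser$bfi)))[2:500]
    fgrid <- (1:499) / 1000
    expect_lt(abs(fgrid[which.max(spec)] - f0), 1 / 1000 + 1e-9)
  }
})

test_that("invalid series parameters name the offending field", {
  expect_error(flow_series_params(duration_s = -1), "duration_s",
               class = "tgflsci_parameter_error")
  expect_error(flow_series_params(tgf_amp = -2), "tgf_amp",
               class = "tgflsci_parameter_error")
  expect_error(flow_series_params(tgf_freq_hz = 0.6), "tgf_freq_hz",
               class = "tgflsci_parameter_error")
  # drift walking out of the Nyquist range over the record
  expect_error(flow_series_params(tgf_freq_hz = 0.03,
                                  tgf_drift_hz_per_s = 1e-3),
               class = "tgflsci_parameter_error")
})

test_that("star flow maps plant the requested number of labeled vessels", {
  empty <- gen_star_flow_map(n_vessels = 0, seed = 1)
  expect_equal(max(empty$mask), 0)
  expect_true(all(empty$map == empty$map[1, 1]))

  m <- gen_star_flow_map(n_vessels = 5, seed = 2)
  expect_setequal(setdiff(unique(as.vector(m$mask)), 0L), 1:5)
  expect_true(all(m$map[m$mask > 0] > m$map[m$mask == 0][1]))
})

test_that("star mask labels agree with a flood-fill connected-component oracle", {
  m <- gen_star_flow_map(n_vessels = 5, seed = 7)
  oracle <- flood_fill_labels(m$mask > 0L)
  expect_identical(partition_signature(m$mask),
                   partition_signature(oracle))
})

test_that("overcrowded placement fails with a placement error", {
  expect_error(
    gen_star_flow_map(n_vessels = 40, image_shape = c(64L, 64L),
                      radius_px = c(10, 12), max_tries = 10L, seed = 1),
    class = "tgflsci_placement_error")
})

test_that("speckle stacks encode the target contrast 1/sqrt(BFI)", {
  # BFI 4 -> K 0.5; single windows are noisy (within 15%), the mean over
  # >= 1000 windows is calibrated (within 2%)
  st <- gen_speckle_stack(matrix(4, 36, 36), duration_s = 2, wire = NULL,
                          seed = 3)
  kc <- temporal_contrast(st, kernel = 25L)
  expect_gt(length(kc), 1000)
  expect_equal(median(kc), 0.5, tolerance = 0.15)  # typical single window
  expect_equal(mean(kc), 0.5, tolerance = 0.02)    # window-averaged
})

test_that("motionless stacks keep the wire centroid fixed", {
  st <- gen_speckle_stack(matrix(25, 48, 48), duration_s = 1, seed = 4)
  # the stamped wire is far darker than any speckle low; a fixed threshold
  # midway recovers it frame by frame
  cents <- sapply(seq_len(dim(st)[3]), function(i) {
    m <- st[, , i] <= 24
    c(mean(row(m)[m]), mean(col(m)[m]))
  })
  expect_lt(max(abs(cents[1, ] - cents[1, 1])), 0.2)
  expect_lt(max(abs(cents[2, ] - cents[2, 1])), 0.2)
})

test_that("sub-unit flow targets are rejected (contrast would exceed 1)", {
  expect_error(gen_speckle_stack(matrix(0.5, 16, 16), duration_s = 1),
               class = "tgflsci_parameter_error")
})

test_that("cohorts honor the drug presets and reproduce with the seed", {
  des <- cohort_design(n_animals = 2, vessels_per_animal = 3,
                       drug = "furosemide",
                       base_params = flow_series_params(duration_s = 400))
  expect_equal(des$mean_shift_frac, 0.113)
  expect_equal(des$amp_scale, 0)
  coh <- gen_cohort(des, seed = 9)
  expect_identical(coh, gen_cohort(des, seed = 9))
  truth <- attr(coh, "truth")
  expect_equal(nrow(truth), 6)
  expect_true(all(truth$tgf_amp_drug == 0))
  expect_equal(truth$mean_bfi_drug / truth$mean_bfi_control,
               rep(1.113, 6))

  # furosemide drug period has no power left at the vessel's TGF frequency
  v1 <- dplyr::filter(coh, vessel_id == 1)
  f1 <- truth$tgf_freq_hz[1]
  amp_at <- function(x) {
    n <- length(x)
    spec <- Mod(fft(x - mean(x)))
    fg <- (seq_len(n) - 1) / n
    spec[which.min(abs(fg - f1))] * 2 / n
  }
  ctl_amp <- amp_at(dplyr::filter(v1, period == "control")$bfi)
  drug_amp <- amp_at(dplyr::filter(v1, period == "drug")$bfi)
  expect_gt(ctl_amp, 5 * drug_amp)
})

test_that("null cohorts have identical generator parameters in both periods", {
  coh <- gen_cohort(cohort_design(n_animals = 2, vessels_per_animal = 2,
                                  drug = "none",
                                  base_params =
                                    flow_series_params(duration_s = 300)),
                    seed = 10)
  truth <- attr(coh, "truth")
  expect_equal(truth$mean_bfi_drug, truth$mean_bfi_control)
  expect_equal(truth$tgf_amp_drug, truth$tgf_amp_control)
})

test_that("furosemide cohorts lower the Sigma metric in every seeded replicate", {
  drops <- vapply(1:20, function(s) {
    coh <- gen_cohort(cohort_design(), seed = 100 + s)
    sig <- coh |>
      dplyr::group_by(animal_id, vessel_id, period) |>
      dplyr::summarise(sigma = sigma_metric(bandpass_tgf(bfi)),
                       .groups = "drop") |>
      dplyr::group_by(period) |>
      dplyr::summarise(m = mean(sigma), .groups = "drop")
    sig$m[sig$period == "drug"] < sig$m[sig$period == "control"]
  }, logical(1))
  expect_equal(sum(drops), 20L)
})
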