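column_sign_agreement <- function(filtered) {
  wide <- tidyr::pivot_wider(filtered, id_cols = "t",
                             names_from = "vessel_id",
                             values_from = "bfi_f")
  m <- as.matrix(wide[, -1])
  mean(apply(m, 1, function(r) max(mean(r > 0), mean(r < 0))))
}

make_vessel_series <- function(phases, duration = 900) {
  purrr::imap_dfr(phases, function(ph, v) {
    gen_flow_series(flow_series_params(duration_s = duration,
                                       tgf_freq_hz = 0.025, tgf_amp = 4,
                                       myo_amp = 0, noise_sd = 0.5,
                                       phase_rad = ph), seed = v) |>
      dplyr::mutate(vessel_id = v)
  })
}

test_that("synchronized vessels produce vertical striations, random phases do not", {
  synced <- add_band_filtered(make_vessel_series(rep(0, 30)))
  expect_gt(column_sign_agreement(synced), 0.9)

  set.seed(41)
  random <- add_band_filtered(
    make_vessel_series(runif(30, 0, 2 * pi)))
  expect_lt(column_sign_agreement(random), 0.6)

  p <- plot_carpet(synced)
  expect_s3_class(p, "ggplot")
})

test_that("metric clouds separate under furosemide and overlap under null", {
  coh <- gen_cohort(cohort_design(n_animals = 3, vessels_per_animal = 12,
                                  drug = "furosemide", animal_sd = 2),
                    seed = 42)
  m <- suppressWarnings(compute_metrics(coh))
  expect_gt(metric_separation(m), 1)

  null_m <- m
  null_m[null_m$period == "drug", c("bfi_mean", "sigma", "auc")] <-
    null_m[null_m$period == "control", c("bfi_mean", "sigma", "auc")]
  expect_lt(metric_separation(null_m), 0.2)

  expect_s3_class(plot_metric_box(m), "ggplot")
  expect_s3_class(plot_metric_scatter3d(m), "trellis")
})

test_that("stacks and series round-trip through TIFF/CSV with their truth", {
  tmp <- withr::local_tempdir()
  st <- gen_speckle_stack(matrix(25, 24, 24), duration_s = 1, seed = 43)
  p <- file.path(tmp, "stack.tif")
  write_stack_tiff(st, p)
  back <- read_stack_tiff(p)
  expect_equal(unclass(back), unclass(st), ignore_attr = TRUE)
  expect_equal(attr(back, "fps"), 50)

  ser <- gen_flow_series(flow_series_params(duration_s = 120), seed = 44)
  sp <- file.path(tmp, "series.csv")
  write_series_csv(ser, sp)
  back_ser <- read_series_csv(sp)
  expect_equal(back_ser$bfi, ser$bfi, tolerance = 1e-12)
  expect_equal(attr(back_ser, "truth")$mean_bfi,
               attr(ser, "truth")$mean_bfi)

  coh <- gen_cohort(cohort_design(n_animals = 2, vessels_per_animal = 2,
                                  base_params =
                                    flow_series_params(duration_s = 60)),
                    seed = 45)
  cp <- file.path(tmp, "cohort.csv")
  write_series_csv(coh, cp)
  back_coh <- read_series_csv(cp)
  expect_equal(as.data.frame(attr(back_coh, "truth")),
               as.data.frame(attr(coh, "truth")), tolerance = 1e-12)
})

test_that("the pipeline runs end to end and reports the sigma decrease", {
  tmp <- withr::local_tempdir()
  cfg <- pipeline_config(
    cohort = cohort_design(n_animals = 2, vessels_per_animal = 10,
                           drug = "furosemide",
                           base_params = flow_series_params(duration_s = 900)),
    seed = 46)
  res <- run_pipeline(cfg, file.path(tmp, "run1"))
  cmp <- res$comparisons
  expect_lt(cmp$estimate[cmp$metric == "sigma"], 0)
  expect_true(file.exists(file.path(tmp, "run1", "metrics.csv")))
  expect_true(file.exists(file.path(tmp, "run1", "manifest.json")))
  expect_true(file.exists(file.path(tmp, "run1", "carpet_control.png")))

  # rerunning the same config reproduces the metrics table byte for byte
  res2 <- run_pipeline(cfg, file.path(tmp, "run2"))
  expect_identical(readLines(file.path(tmp, "run1", "metrics.csv")),
                   readLines(file.path(tmp, "run2", "metrics.csv")))

  expect_error(run_pipeline(cfg, file.path(tmp, "missing", "nested", "x")),
               class = "tgflsci_io_error")
})

test_that("the imaging-side demo recovers vessels and their series", {
  tmp <- withr::local_tempdir()
  cfg <- pipeline_config(
    cohort = cohort_design(n_animals = 2, vessels_per_animal = 4,
                           base_params = flow_series_params(duration_s = 400)),
    stack_demo = TRUE, stack_px = 96L, stack_duration_s = 30L, seed = 47)
  res <- run_pipeline(cfg, file.path(tmp, "demo"))
  expect_gte(max(res$demo$mask), 1)
  expect_true(all(res$demo$series$bfi > 0))
  expect_true(file.exists(file.path(tmp, "demo", "demo_series.csv")))
})
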