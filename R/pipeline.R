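#' Pipeline configuration
#'
#' Assembles every knob of the analysis into one validated object that is
#' serialized into the output directory of each run, so results are
#' auditable and reproducible from config + seed alone.
#'
#' @param cohort A [cohort_design()] describing the simulated experiment
#'   (series-level entry), or `NULL`.
#' @param stack_demo If `TRUE`, also run a small imaging-side demonstration
#'   (synthetic speckle stack -> registration -> contrast -> segmentation ->
#'   extraction) and include its recovered series in the outputs.
#' @param stack_px,stack_duration_s Size of that demonstration stack.
#' @param kernel Temporal contrast kernel, frames.
#' @param band,baseline_band TGF and baseline bands, Hz.
#' @param superlet [superlet_params()] used for metric spectra.
#' @param rel_threshold,min_area Segmentation parameters.
#' @param alpha Significance threshold for comparisons.
#' @param seed Integer seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_design(),
                            stack_demo = FALSE, stack_px = 96L,
                            stack_duration_s = 60L, kernel = 25L,
                            band = c(0.015, 0.04),
                            baseline_band = c(0.04, 0.05),
                            superlet = superlet_params(f_min = 0.01,
                                                       f_max = 0.06),
                            rel_threshold = 0.3, min_area = 20L,
                            alpha = 0.001, seed = 1L) {
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_design"))
  stopifnot(inherits(superlet, "superlet_params"))
  structure(list(cohort = cohort, stack_demo = stack_demo,
                 stack_px = as.integer(stack_px),
                 stack_duration_s = as.integer(stack_duration_s),
                 kernel = check_count(kernel, "kernel", 2L),
                 band = band, baseline_band = baseline_band,
                 superlet = superlet, rel_threshold = rel_threshold,
                 min_area = min_area, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Series-level path: simulate the cohort, compute per-vessel metrics,
#' compare periods with the mixed model, and write figures. Imaging-side
#' path (`stack_demo = TRUE`): additionally synthesize a speckle stack with
#' breathing motion and a wire fiducial, register it, convert to 1 Hz BFI,
#' segment star vessels, and extract their series. All numerical results
#' are written as CSV/JSON before any figure; a manifest records
#' parameters, seed, and output hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `metrics`, `comparisons` (tibble), and
#'   the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir) || is.null(out_dir)) {
    abort("`out_dir` is required.", class = "tgflsci_contract_error")
  }
  parent <- dirname(out_dir)
  if (!dir.exists(parent)) {
    abort(sprintf("Output parent directory does not exist: %s", parent),
          class = "tgflsci_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "tgflsci_pipeline_error")
    })
  }

  results <- list(out_dir = out_dir)

  if (isTRUE(config$stack_demo)) {
    demo <- stage("imaging_demo", pipeline_stack_demo(config))
    write_table_csv(demo$series, file.path(out_dir, "demo_series.csv"))
    write_table_csv(demo$transforms, file.path(out_dir,
                                               "demo_transforms.csv"))
    results$demo <- demo
  }

  cohort <- stage("simulate",
                  gen_cohort(config$cohort, seed = config$seed))
  write_series_csv(cohort, file.path(out_dir, "cohort_series.csv"))

  metrics <- stage("metrics",
                   suppressWarnings(compute_metrics(
                     cohort, band = config$band,
                     baseline_band = config$baseline_band,
                     superlet = config$superlet)))
  write_table_csv(metrics, file.path(out_dir, "metrics.csv"))

  comparisons <- stage("compare", dplyr::bind_rows(lapply(
    c("bfi_mean", "sigma", "auc"), function(m) {
      tidy(compare_periods_lme(metrics, m, alpha = config$alpha))
    })))
  write_table_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  jsonlite::write_json(comparisons, file.path(out_dir, "comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  stage("figures", {
    filtered <- add_band_filtered(
      dplyr::filter(cohort, .data$period == "control"), band = config$band)
    ggplot2::ggsave(file.path(out_dir, "carpet_control.png"),
                    plot_carpet(filtered), width = 7, height = 5, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "metric_boxes.png"),
                    plot_metric_box(metrics), width = 7, height = 4,
                    dpi = 120)
    grDevices::png(file.path(out_dir, "metric_scatter3d.png"),
                   width = 700, height = 600)
    print(plot_metric_scatter3d(metrics))
    grDevices::dev.off()
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tgflsci")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = serialize_config(config),
    outputs = vapply(
      list.files(out_dir, full.names = TRUE),
      function(p) unname(as.character(tools::md5sum(p))), character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  results$metrics <- metrics
  results$comparisons <- comparisons
  invisible(results)
}

# Imaging-side demonstration: star map -> speckle stack with sinusoidal
# breathing motion -> register -> 1 Hz BFI -> segment -> extract.
pipeline_stack_demo <- function(config) {
  px <- config$stack_px
  m <- gen_star_flow_map(n_vessels = 3,
                         image_shape = c(px, px),
                         bg_bfi = 30, vessel_bfi = 60,
                         seed = config$seed)
  nf <- config$stack_duration_s * 50L
  breath <- cbind(2 * sin(2 * pi * (1:nf) / 60),   # ~0.8 Hz breathing at 50 fps
                  1.5 * cos(2 * pi * (1:nf) / 60))
  st <- gen_speckle_stack(m$map, duration_s = config$stack_duration_s,
                          motion = breath, seed = config$seed + 1L)
  reg <- register_stack(st)
  bfi <- stack_to_bfi(reg, kernel = config$kernel)
  fmap <- average_flow_map(bfi)
  mask <- segment_vessels(fmap, rel_threshold = config$rel_threshold,
                          min_area = config$min_area)
  series <- extract_timeseries(bfi, mask, period = "control")
  list(series = series, transforms = attr(reg, "transforms"),
       mask = mask, flow_map = fmap, truth = m)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$cohort <- if (!is.null(out$cohort)) {
    ch <- unclass(out$cohort)
    ch$base_params <- unclass(ch$base_params)
    ch
  }
  out$superlet <- unclass(out$superlet)
  out
}
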