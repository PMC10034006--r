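# Serialization: stacks as multi-page TIFF, tables as CSV with JSON
# sidecars echoing generator/processing parameters.

#' Write / read a speckle or flow stack as multi-page TIFF
#'
#' Raw speckle stacks are stored as 8-bit pages, flow (BFI) stacks as
#' 32-bit float pages; acquisition metadata travels in a JSON sidecar
#' (`<path>.json`).
#'
#' @param stack A `speckle_stack` or `bfi_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  is_raw <- inherits(stack, "speckle_stack")
  pages <- lapply(seq_len(dim(stack)[3]), function(i) {
    m <- unclass(stack)[, , i]
    if (is_raw) m / 255 else m
  })
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (is_raw) 8L else 32L,
                  reduce = FALSE)
  meta <- list(
    type = if (is_raw) "speckle_stack" else "bfi_stack",
    fps = attr(stack, "fps"), rate = attr(stack, "rate"),
    exposure_ms = attr(stack, "exposure_ms"),
    kernel = attr(stack, "kernel"), k_min = attr(stack, "k_min"),
    dim = dim(stack))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (identical(meta$type, "speckle_stack")) {
    speckle_stack(round(arr * 255), fps = meta$fps,
                  exposure_ms = meta$exposure_ms)
  } else {
    structure(arr, rate = meta$rate, kernel = meta$kernel,
              k_min = meta$k_min, class = "bfi_stack")
  }
}

#' Write / read a flow-series table with its generator truth
#'
#' Series go to long-format CSV; the `"truth"` and `"design"` attributes
#' (generator parameters) go to a JSON sidecar so every synthetic artifact
#' round-trips with its ground truth.
#'
#' @param series Series tibble (e.g. from [gen_flow_series()] or
#'   [gen_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(series, path)
  truth <- attr(series, "truth")
  deep_unclass <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), deep_unclass))
    x
  }
  sidecar <- list(
    truth = deep_unclass(truth),
    truth_is_table = is.data.frame(truth),
    design = deep_unclass(attr(series, "design")))
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    truth <- side$truth
    if (isTRUE(side$truth_is_table)) truth <- as_tibble(as.data.frame(truth))
    attr(out, "truth") <- truth
    attr(out, "design") <- side$design
  }
  out
}

#' Write a transform series or metrics table to CSV
#'
#' @param x A tibble (`transform_series`, metrics, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
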