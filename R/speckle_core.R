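#' Temporal speckle contrast
#'
#' Per pixel, computes K = sd/mean of raw intensity over consecutive
#' *non-overlapping* windows of `kernel` frames (sample, n-1, standard
#' deviation). At 50 Hz with the default 25-frame kernel this yields two
#' contrast images per second. Moving blood cells blur the speckle within
#' the window, so lower K means higher flow.
#'
#' @param stack An aligned [speckle_stack()] with at least `kernel` frames.
#' @param kernel Temporal window length in frames (default 25).
#' @return A `contrast_stack`: array `[rows, cols, windows]` with attributes
#'   `rate` (windows per second) and `kernel`.
#' @export
temporal_contrast <- function(stack, kernel = 25L) {
  stopifnot(inherits(stack, "speckle_stack"))
  kernel <- check_count(kernel, "kernel", lower = 2L)
  nf <- n_frames(stack)
  if (nf < kernel) {
    abort(sprintf("Stack has %d frames; kernel needs >= %d.", nf, kernel),
          class = "tgflsci_contract_error")
  }
  nw <- nf %/% kernel
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  k <- array(0, dim = c(nr, nc, nw))
  x <- unclass(stack)
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * kernel + 1L):(w * kernel)
    blk <- x[, , idx, drop = FALSE]
    mu <- rowMeans(blk, dims = 2)
    # sample sd via E[x^2] with Bessel correction
    ss <- rowSums(blk^2, dims = 2)
    v <- pmax((ss - kernel * mu^2) / (kernel - 1), 0)
    k[, , w] <- sqrt(v) / mu
  }
  structure(k, rate = attr(stack, "fps") / kernel, kernel = kernel,
            class = "contrast_stack")
}

#' Convert speckle contrast to blood flow index
#'
#' BFI = 1/K^2 with K clamped below at `k_min` so static pixels (K = 0)
#' map to a large finite flow index instead of infinity.
#'
#' @param contrast A `contrast_stack` (or numeric array/matrix of K values).
#' @param k_min Clamp floor for K (default 1e-3; never reached on realistic
#'   speckle).
#' @return Flow-index values of the same shape; for a `contrast_stack`
#'   input, a `bfi_stack` at the contrast-window rate carrying `k_min` and
#'   `kernel` provenance attributes.
#' @examples
#' contrast_to_bfi(matrix(c(1, 0.5), 1))  # 1 and 4
#' @export
contrast_to_bfi <- function(contrast, k_min = 1e-3) {
  check_number(k_min, "k_min", lower = 1e-12)
  if (any(contrast < 0)) {
    abort("Contrast must be >= 0.", class = "tgflsci_contract_error")
  }
  bfi <- 1 / pmax(contrast, k_min)^2
  if (inherits(contrast, "contrast_stack")) {
    structure(bfi, rate = attr(contrast, "rate"),
              kernel = attr(contrast, "kernel"), k_min = k_min,
              class = "bfi_stack")
  } else {
    bfi
  }
}

#' Subsample a flow stack to 1 Hz
#'
#' Averages the contrast-window flow images within each second (arithmetic
#' mean), completing the 50 Hz raw -> 1 Hz flow pipeline.
#'
#' @param flow A `bfi_stack` whose `rate` is an integer number of windows
#'   per second.
#' @return A `bfi_stack` at 1 Hz with `floor(duration_s)` frames.
#' @export
subsample_to_1hz <- function(flow) {
  stopifnot(inherits(flow, "bfi_stack"))
  rate <- attr(flow, "rate")
  if (is.null(rate) || abs(rate - round(rate)) > 1e-9 || rate < 1) {
    abort("Flow stack rate must be an integer number of windows per second.",
          class = "tgflsci_contract_error")
  }
  rate <- round(rate)
  if (rate == 1) return(flow)
  nw <- dim(flow)[3]
  ns <- nw %/% rate
  nr <- dim(flow)[1]; nc <- dim(flow)[2]
  out <- array(0, dim = c(nr, nc, ns))
  x <- unclass(flow)
  for (s in seq_len(ns)) {
    idx <- ((s - 1L) * rate + 1L):(s * rate)
    out[, , s] <- rowMeans(x[, , idx, drop = FALSE], dims = 2)
  }
  structure(out, rate = 1, kernel = attr(flow, "kernel"),
            k_min = attr(flow, "k_min"), class = "bfi_stack")
}

#' Time-averaged flow map
#'
#' Per-pixel temporal mean of a 1 Hz flow stack over `[t_start, t_end)`
#' seconds; the map on which star vessels are segmented.
#'
#' @param bfi A `bfi_stack` at 1 Hz.
#' @param t_start,t_end Averaging window in seconds (defaults: full record).
#' @return Numeric matrix (the flow map).
#' @export
average_flow_map <- function(bfi, t_start = 0, t_end = NULL) {
  stopifnot(inherits(bfi, "bfi_stack"))
  ns <- dim(bfi)[3]
  t_end <- t_end %||% ns
  i0 <- floor(t_start) + 1L
  i1 <- ceiling(t_end)
  if (i0 > i1 || i0 < 1L || i1 > ns || t_start >= t_end) {
    abort("Averaging window is empty or outside the record.",
          class = "tgflsci_contract_error")
  }
  rowMeans(unclass(bfi)[, , i0:i1, drop = FALSE], dims = 2)
}

#' Full imaging-side conversion: aligned stack to 1 Hz flow stack
#'
#' Convenience composition of [temporal_contrast()], [contrast_to_bfi()]
#' and [subsample_to_1hz()].
#'
#' @inheritParams temporal_contrast
#' @inheritParams contrast_to_bfi
#' @return A 1 Hz `bfi_stack`.
#' @export
stack_to_bfi <- function(stack, kernel = 25L, k_min = 1e-3) {
  subsample_to_1hz(contrast_to_bfi(temporal_contrast(stack, kernel), k_min))
}
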