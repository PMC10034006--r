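#' Raw speckle frame stack
#'
#' Wraps a `rows x cols x frames` numeric array of raw speckle intensities
#' with its acquisition metadata (frame rate, exposure). The imaging default
#' mirrors a high-speed CMOS acquisition: 50 Hz, 5 ms exposure, 8-bit.
#'
#' @param frames Numeric 3-D array `[rows, cols, frames]`.
#' @param fps Acquisition rate, frames per second.
#' @param exposure_ms Exposure time per frame, milliseconds.
#' @return A `speckle_stack` object.
#' @export
speckle_stack <- function(frames, fps = 50, exposure_ms = 5) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  check_number(fps, "fps", lower = 1e-9)
  structure(frames, fps = fps, exposure_ms = exposure_ms,
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<speckle_stack> %d x %d px, %d frames @ %g Hz (%.1f s)\n",
              d[1], d[2], d[3], attr(x, "fps"), d[3] / attr(x, "fps")))
  invisible(x)
}

n_frames <- function(stack) dim(stack)[3]

#' Myograph-wire fiducial geometry
#'
#' A thin dark wire bent at an acute angle, laid over the field of view; it
#' is the stationary landmark used to track breathing motion. Coordinates
#' are fractions of the frame size.
#'
#' @param start `c(y, x)` of the bend point, fractional.
#' @param angles Directions of the two wire arms, radians.
#' @param lengths Arm lengths as fractions of the smaller frame dimension.
#' @param thickness_px Wire thickness in pixels.
#' @param intensity Stamped wire intensity (dark, 8-bit scale).
#' @return A list of class `wire_spec`.
#' @export
wire_spec <- function(start = c(0.30, 0.25), angles = c(0.35, 1.85),
                      lengths = c(0.55, 0.45), thickness_px = 5,
                      intensity = 16) {
  structure(list(start = start, angles = angles, lengths = lengths,
                 thickness_px = thickness_px, intensity = intensity),
            class = "wire_spec")
}

# Logical wire mask for an (nr, nc) frame.
wire_mask <- function(wire, nr, nc) {
  stamp <- matrix(FALSE, nr, nc)
  half <- (wire$thickness_px - 1) / 2
  y0 <- wire$start[1] * nr
  x0 <- wire$start[2] * nc
  for (k in seq_along(wire$angles)) {
    len <- wire$lengths[k] * min(nr, nc)
    steps <- seq(0, len, by = 0.5)
    ys <- y0 + steps * sin(wire$angles[k])
    xs <- x0 + steps * cos(wire$angles[k])
    for (i in seq_along(steps)) {
      rr <- round(ys[i] + (-half:half))
      cc <- round(xs[i] + (-half:half))
      rr <- rr[rr >= 1 & rr <= nr]
      cc <- cc[cc >= 1 & cc <= nc]
      stamp[rr, cc] <- TRUE
    }
  }
  stamp
}

#' Generate a dynamic speckle stack encoding a target flow map
#'
#' Synthesizes raw frames whose *temporal* statistics encode flow: per pixel,
#' intensities are drawn i.i.d. from a gamma distribution with coefficient of
#' variation \eqn{K = 1/\sqrt{BFI}} (so the 25-frame temporal contrast
#' recovers the flow map), a dark wire fiducial is stamped on every frame,
#' the whole frame is translated by the per-frame motion, and intensities are
#' quantized to 8 bits. The stamped mean intensity (default 64) leaves
#' headroom so the 8-bit clamp stays inactive down to the generator's minimum
#' admissible flow (BFI = 1).
#'
#' @param flow_maps A single numeric matrix (constant flow) or a list of
#'   matrices, one per second of recording. All BFI values must be >= 1
#'   (contrast cannot exceed 1 for this generator).
#' @param duration_s Record length in seconds; defaults to `length(flow_maps)`
#'   when a list is given, otherwise required.
#' @param fps Frame rate (default 50).
#' @param motion Optional `n_frames x 2` matrix of per-frame `(dx, dy)`
#'   translations in pixels (breathing motion). `NULL` means motionless.
#' @param wire A [wire_spec()] or `NULL` to omit the fiducial.
#' @param mean_intensity Stamped mean speckle intensity (8-bit scale).
#' @param seed Optional integer seed.
#' @return A [speckle_stack()] with attribute `"truth"`: the per-frame
#'   motion, the wire mask, and the per-pixel target contrast.
#' @examples
#' st <- gen_speckle_stack(matrix(25, 32, 32), duration_s = 1, seed = 1)
#' dim(st)
#' @export
gen_speckle_stack <- function(flow_maps, duration_s = NULL, fps = 50,
                              motion = NULL, wire = wire_spec(),
                              mean_intensity = 64, seed = NULL) {
  if (is.matrix(flow_maps)) {
    if (is.null(duration_s)) {
      abort("`duration_s` is required when `flow_maps` is a single matrix.",
            class = "tgflsci_parameter_error")
    }
    flow_maps <- replicate(duration_s, flow_maps, simplify = FALSE)
  }
  duration_s <- length(flow_maps)
  check_count(fps, "fps", lower = 1L)
  nr <- nrow(flow_maps[[1]]); nc <- ncol(flow_maps[[1]])
  if (any(vapply(flow_maps, function(m) any(m < 1), logical(1)))) {
    abort(paste0("`flow_maps` contains BFI_target < 1: target contrast ",
                 "K = 1/sqrt(BFI) would exceed 1."),
          class = "tgflsci_parameter_error")
  }
  n_total <- duration_s * fps
  if (is.null(motion)) motion <- matrix(0, n_total, 2)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_total || ncol(motion) != 2) {
    abort("`motion` must be an n_frames x 2 matrix of (dx, dy).",
          class = "tgflsci_contract_error")
  }
  wmask <- if (!is.null(wire)) wire_mask(wire, nr, nc) else
    matrix(FALSE, nr, nc)

  with_seed_or_current(seed, {
    frames <- array(0, dim = c(nr, nc, n_total))
    for (s in seq_len(duration_s)) {
      shape <- flow_maps[[s]]             # CV = 1/sqrt(shape) = K_target
      scl <- mean_intensity / shape
      # draws recycle the per-pixel shape across the fps frames of second s
      draws <- rgamma(nr * nc * fps, shape = as.vector(shape),
                      rate = 1 / as.vector(scl))
      blk <- array(draws, dim = c(nr, nc, fps))
      for (j in seq_len(fps)) {
        i <- (s - 1L) * fps + j
        fr <- blk[, , j]
        if (!is.null(wire)) fr[wmask] <- wire$intensity
        if (motion[i, 1] != 0 || motion[i, 2] != 0) {
          fr <- translate_image(fr, motion[i, 1], motion[i, 2],
                                fill = mean_intensity)
        }
        frames[, , i] <- pmin(pmax(round(fr), 1), 255)
      }
    }
    out <- speckle_stack(frames, fps = fps)
    attr(out, "truth") <- list(
      motion = motion, wire_mask = wmask,
      k_target = lapply(flow_maps, function(m) 1 / sqrt(m)),
      mean_intensity = mean_intensity, seed = seed)
    out
  })
}
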