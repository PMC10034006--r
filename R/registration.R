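#' Binarize the wire fiducial in a speckle frame
#'
#' Separates the dark myograph wire from the bright speckle background by
#' thresholding. An optional box blur (radius in pixels) suppresses speckle
#' fluctuation before thresholding, which is essential on raw frames where
#' per-pixel intensities vary as much as the wire/background contrast.
#'
#' @param frame Numeric matrix of raw intensities.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param smooth_radius Box-blur radius applied before thresholding
#'   (0 = none; the wire itself must be thicker than `2 * smooth_radius`).
#' @param prob Foreground quantile for `method = "quantile"`.
#' @return Logical matrix, `TRUE` on the wire.
#' @export
binarize_fiducial <- function(frame, method = c("otsu", "quantile"),
                              smooth_radius = 0, prob = 0.05) {
  method <- match.arg(method)
  if (length(frame) == 0L) {
    abort("`frame` is empty.", class = "tgflsci_contract_error")
  }
  if (diff(range(frame)) == 0) {
    abort("Fiducial not found: frame has constant intensity.",
          class = "tgflsci_fiducial_error")
  }
  sm <- box_blur(frame, smooth_radius)
  thr <- fiducial_threshold(sm, method, prob)
  mask <- sm < thr
  frac <- mean(mask)
  if (frac <= 0 || frac >= 0.5) {
    abort(sprintf(
      "Fiducial not found: foreground fraction %.2f outside (0, 0.5).", frac),
      class = "tgflsci_fiducial_error")
  }
  mask
}

fiducial_threshold <- function(sm, method = "otsu", prob = 0.05) {
  switch(method,
    otsu = {
      lo <- min(sm); hi <- max(sm)
      img <- EBImage::Image((sm - lo) / (hi - lo))
      EBImage::otsu(img, range = c(0, 1)) * (hi - lo) + lo
    },
    quantile = unname(quantile(sm, prob))
  )
}

# Soft fiducial map: graded darkness below the wire threshold. Unlike the
# hard binary mask this keeps subpixel edge information for registration.
fiducial_softmask <- function(frame, smooth_radius = 2) {
  if (diff(range(frame)) == 0) {
    abort("Fiducial not found: frame has constant intensity.",
          class = "tgflsci_fiducial_error")
  }
  sm <- box_blur(frame, smooth_radius)
  thr <- fiducial_threshold(sm)
  soft <- pmax(thr - sm, 0)
  frac <- mean(soft > 0)
  if (frac <= 0 || frac >= 0.5) {
    abort(sprintf(
      "Fiducial not found: foreground fraction %.2f outside (0, 0.5).", frac),
      class = "tgflsci_fiducial_error")
  }
  soft
}

# Phase correlation between two equally sized masks/images. Returns
# c(dx, dy) such that img(y, x) ~ ref(y - dy, x - dx), with quadratic
# subpixel refinement of the correlation peak.
phase_corr_shift <- function(ref, img) {
  nr <- nrow(ref); nc <- ncol(ref)
  fr <- fft(ref); fi <- fft(img)
  cp <- fr * Conj(fi)
  mag <- Mod(cp)
  r <- Re(fft(cp / (mag + 1e-12 * max(mag)), inverse = TRUE)) / (nr * nc)
  p <- which(r == max(r), arr.ind = TRUE)[1, ]
  refine <- function(vals) {
    den <- 2 * (2 * vals[2] - vals[1] - vals[3])
    if (abs(den) < 1e-30) return(0)
    d <- (vals[3] - vals[1]) / den
    max(min(d, 0.5), -0.5)
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy_int <- p[1] - 1; dx_int <- p[2] - 1
  sub_y <- refine(r[wrap(p[1] + c(-1, 0, 1), nr), p[2]])
  sub_x <- refine(r[p[1], wrap(p[2] + c(-1, 0, 1), nc)])
  dy <- dy_int + sub_y
  dx <- dx_int + sub_x
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = unname(-dx), dy = unname(-dy))
}

#' Estimate per-frame motion from the wire fiducial
#'
#' Tracks in-plane breathing/visceral motion by extracting a soft wire map
#' (graded darkness below the wire threshold, which keeps subpixel edge
#' information) in every frame and phase-correlating it against the first
#' frame's map, with quadratic subpixel peak refinement. Frames where the
#' fiducial cannot be found are interpolated from neighbors when they are
#' few; if more than
#' `max_lost_frac` of frames lose the fiducial, estimation aborts listing
#' the offending frame indices.
#'
#' @param stack A [speckle_stack()] (>= 2 frames).
#' @param smooth_radius Pre-threshold blur radius passed to
#'   [binarize_fiducial()]; the default 2 suppresses speckle noise.
#' @param max_lost_frac Tolerated fraction of fiducial-less frames.
#' @return A tibble (`frame`, `dx`, `dy`) of class `transform_series`;
#'   row 1 is the identity.
#' @export
estimate_transforms <- function(stack, smooth_radius = 2,
                                max_lost_frac = 0.05) {
  stopifnot(inherits(stack, "speckle_stack"))
  nf <- n_frames(stack)
  if (nf < 2L) {
    abort("Need at least 2 frames.", class = "tgflsci_contract_error")
  }
  ref <- fiducial_softmask(stack[, , 1], smooth_radius = smooth_radius)
  dx <- dy <- rep(NA_real_, nf)
  dx[1] <- dy[1] <- 0
  lost <- integer(0)
  for (i in 2:nf) {
    m <- tryCatch(
      fiducial_softmask(stack[, , i], smooth_radius = smooth_radius),
      tgflsci_fiducial_error = function(e) NULL)
    if (is.null(m)) {
      lost <- c(lost, i)
    } else {
      sh <- phase_corr_shift(ref, m)
      dx[i] <- sh["dx"]; dy[i] <- sh["dy"]
    }
  }
  if (length(lost) > max_lost_frac * nf) {
    abort(paste0("Fiducial lost in ", length(lost), " of ", nf, " frames: ",
                 paste(head(lost, 20), collapse = ", "),
                 if (length(lost) > 20) ", ..."),
          class = "tgflsci_registration_error")
  }
  if (length(lost)) {
    ok <- setdiff(seq_len(nf), lost)
    dx[lost] <- approx(ok, dx[ok], xout = lost, rule = 2)$y
    dy[lost] <- approx(ok, dy[ok], xout = lost, rule = 2)$y
  }
  structure(tibble(frame = seq_len(nf), dx = dx, dy = dy),
            class = c("transform_series", class(tibble())))
}

#' Align a stack to its first frame
#'
#' Translates frame *i* by `-(dx_i, dy_i)` (bilinear interpolation; exposed
#' borders filled with the frame median so border contrast windows stay
#' finite). Frame 1 is returned unchanged.
#'
#' @param stack A [speckle_stack()].
#' @param transforms A `transform_series` from [estimate_transforms()] (or a
#'   tibble with columns `dx`, `dy`), one row per frame.
#' @return The aligned [speckle_stack()].
#' @export
apply_transforms <- function(stack, transforms) {
  stopifnot(inherits(stack, "speckle_stack"))
  nf <- n_frames(stack)
  if (nrow(transforms) != nf) {
    abort(sprintf("Transform count (%d) != frame count (%d).",
                  nrow(transforms), nf),
          class = "tgflsci_contract_error")
  }
  out <- unclass(stack)
  for (i in seq_len(nf)) {
    if (transforms$dx[i] == 0 && transforms$dy[i] == 0) next
    fr <- stack[, , i]
    out[, , i] <- translate_image(fr, -transforms$dx[i], -transforms$dy[i],
                                  fill = stats::median(fr))
  }
  speckle_stack(out, fps = attr(stack, "fps"),
                exposure_ms = attr(stack, "exposure_ms"))
}

#' Register a stack (estimate + apply) in one step
#'
#' @inheritParams estimate_transforms
#' @return The aligned stack, with the estimated `transform_series` in
#'   attribute `"transforms"`.
#' @export
register_stack <- function(stack, smooth_radius = 2, max_lost_frac = 0.05) {
  tr <- estimate_transforms(stack, smooth_radius = smooth_radius,
                            max_lost_frac = max_lost_frac)
  out <- apply_transforms(stack, tr)
  attr(out, "transforms") <- tr
  out
}
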