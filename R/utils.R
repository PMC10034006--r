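# Shared internals: seeded evaluation, parameter checks, image translation.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state. seed = NULL uses (and advances) the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "tgflsci_parameter_error")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper),
          class = "tgflsci_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower),
          class = "tgflsci_parameter_error")
  }
  invisible(as.integer(x))
}

# Translate a matrix by (dx, dy) with bilinear interpolation. dx moves
# content toward larger column indices (x), dy toward larger row indices
# (y). Exposed borders are filled with `fill`. Integer shifts resample
# exactly (no smoothing).
translate_image <- function(mat, dx, dy, fill = stats::median(mat)) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  # source coordinates for each output pixel
  ys <- seq_len(nr) - dy
  xs <- seq_len(nc) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0

  # out-of-field source pixels contribute the fill value
  at <- function(rr, cc) {
    m <- mat[pmin(pmax(rr, 1L), nr), pmin(pmax(cc, 1L), nc), drop = FALSE]
    m[rr < 1L | rr > nr, ] <- fill
    m[, cc < 1L | cc > nc] <- fill
    m
  }
  w00 <- outer(1 - fy, 1 - fx)
  w10 <- outer(fy, 1 - fx)
  w01 <- outer(1 - fy, fx)
  w11 <- outer(fy, fx)
  at(y0, x0) * w00 + at(y0 + 1L, x0) * w10 +
    at(y0, x0 + 1L) * w01 + at(y0 + 1L, x0 + 1L) * w11
}

# Mean (box) filter with replicated borders; radius 0 is a no-op.
box_blur <- function(mat, radius) {
  if (radius <= 0) return(mat)
  side <- 2L * radius + 1L
  kern <- matrix(1 / side^2, side, side)
  EBImage::filter2(mat, kern, boundary = "replicate")
}

# Trapezoidal integral of y over x restricted to [lo, hi] (grid points
# assumed to include samples inside the band; endpoints interpolated if
# not on the grid).
band_trapz <- function(x, y, lo, hi) {
  # frequencies reported missing (no edge-free cells) are omitted
  keep <- !is.na(y)
  x <- x[keep]
  y <- y[keep]
  sel <- x >= lo & x <= hi
  xs <- x[sel]
  ys <- y[sel]
  if (!any(sel) || min(xs) > lo) {
    if (lo >= min(x) && lo <= max(x)) {
      xs <- c(lo, xs); ys <- c(approx(x, y, lo)$y, ys)
    }
  }
  if (max(xs) < hi && hi <= max(x)) {
    xs <- c(xs, hi); ys <- c(ys, approx(x, y, hi)$y)
  }
  if (length(xs) < 2L) {
    abort("Band is not covered by the frequency grid.",
          class = "tgflsci_contract_error")
  }
  pracma::trapz(xs, ys)
}
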