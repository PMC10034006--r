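#' Generate a flow map with star-shaped vessels
#'
#' Builds a time-averaged blood-flow-index map as seen on the renal surface:
#' a uniform background with `n_vessels` non-overlapping stellate regions of
#' elevated flow, each made of 4--8 straight branches radiating from a
#' center. Such "star vessels" sit downstream of efferent arterioles and are
#' the segmented unit of observation.
#'
#' @param n_vessels Number of vessels to plant (0 gives a uniform map).
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param bg_bfi Background flow level (BFI units).
#' @param vessel_bfi Vessel flow level; must exceed `bg_bfi`.
#' @param noise_sd SD of additive Gaussian map noise (default 0).
#' @param radius_px Range of branch lengths, pixels.
#' @param thickness_px Branch thickness (pixels, >= 3 so that the
#'   morphological opening used downstream does not sever branches).
#' @param max_tries Placement retries before giving up.
#' @param seed Optional integer seed.
#' @return A list of class `star_flow_map` with elements `map` (numeric
#'   matrix), `mask` (integer label matrix, 0 = background, 1..n = vessels),
#'   and `truth` (per-vessel centers and geometry).
#' @examples
#' m <- gen_star_flow_map(n_vessels = 3, seed = 1)
#' table(m$mask)
#' @export
gen_star_flow_map <- function(n_vessels = 5, image_shape = c(128L, 128L),
                              bg_bfi = 30, vessel_bfi = 60, noise_sd = 0,
                              radius_px = c(10, 16), thickness_px = 3,
                              max_tries = 200L, seed = NULL) {
  check_count(n_vessels, "n_vessels", lower = 0L)
  check_number(bg_bfi, "bg_bfi", lower = 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (vessel_bfi <= bg_bfi) {
    abort("`vessel_bfi` must exceed `bg_bfi`.",
          class = "tgflsci_parameter_error")
  }
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  rmax <- max(radius_px) + thickness_px
  if (2 * rmax >= min(nr, nc)) {
    abort("Vessels do not fit in `image_shape`.",
          class = "tgflsci_parameter_error")
  }
  with_seed_or_current(seed, {
    mask <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)  # stars + clearance margin
    centers <- list()
    for (v in seq_len(n_vessels)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cy <- runif(1, rmax + 1, nr - rmax)
        cx <- runif(1, rmax + 1, nc - rmax)
        stamp <- star_stamp(nr, nc, cy, cx,
                            n_branches = sample(4:8, 1),
                            radius = runif(1, radius_px[1], radius_px[2]),
                            thickness = thickness_px)
        margin <- EBImage::dilate(stamp * 1,
                                  EBImage::makeBrush(7, "disc")) > 0
        if (!any(margin & occupied)) {
          mask[stamp] <- v
          occupied <- occupied | margin
          centers[[v]] <- c(y = cy, x = cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "Could not place vessel %d without overlap after %d tries.",
          v, max_tries), class = "tgflsci_placement_error")
      }
    }
    map <- matrix(bg_bfi, nr, nc)
    map[mask > 0L] <- vessel_bfi
    if (noise_sd > 0) map <- map + rnorm(nr * nc, sd = noise_sd)
    structure(
      list(map = map, mask = mask,
           truth = list(centers = centers, bg_bfi = bg_bfi,
                        vessel_bfi = vessel_bfi, noise_sd = noise_sd,
                        seed = seed)),
      class = "star_flow_map")
    })
}

# Rasterize one star: n_branches segments from (cy, cx), random angles,
# stamped with a square pen of the given thickness. Returns logical matrix.
star_stamp <- function(nr, nc, cy, cx, n_branches, radius, thickness) {
  stamp <- matrix(FALSE, nr, nc)
  half <- (thickness - 1) / 2
  angles <- runif(1) * 2 * pi + seq(0, 2 * pi, length.out = n_branches + 1)[-1]
  for (a in angles) {
    steps <- seq(0, radius, by = 0.5)
    ys <- cy + steps * sin(a)
    xs <- cx + steps * cos(a)
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
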