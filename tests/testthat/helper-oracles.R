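# Independent oracles used across tests: these deliberately avoid the
# package's own implementation paths.

# Brute-force 4-connected component labeling by flood fill.
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- ((i - 1L) %% nr) + 1L
      cl <- ((i - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cl + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# Partition signature invariant to label permutation.
partition_signature <- function(lab) {
  px <- which(lab > 0L)
  split(px, lab[px]) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, min, numeric(1)))])() |>
    unname()
}

# Direct O(n*m) time-domain complex Morlet convolution ("same" alignment),
# matching a unit-energy wavelet with envelope SD cycles/(k_sd * f).
direct_morlet_mag <- function(x, f, cycles, rate = 1, k_sd = 5) {
  b <- cycles / (k_sd * f)
  half <- ceiling(4 * b * rate)
  tt <- (-half:half) / rate
  psi <- exp(-tt^2 / (2 * b^2)) * exp(2i * pi * f * tt)
  psi <- psi / sqrt(sum(Mod(psi)^2) / rate)
  n <- length(x)
  out <- complex(n)
  for (k in seq_len(n)) {
    acc <- 0 + 0i
    for (j in seq_along(tt)) {
      src <- k - (j - half - 1L)
      if (src >= 1L && src <= n) acc <- acc + x[src] * psi[j]
    }
    out[k] <- acc
  }
  Mod(out)
}

# Circular array roll: content moves by +dx columns, +dy rows.
roll_frame <- function(m, dx, dy) {
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

# Dice coefficient between a predicted label and the best-matching truth
# label.
best_dice <- function(pred_mask, truth_mask, pred_label) {
  truth_labels <- setdiff(unique(as.vector(truth_mask)), 0L)
  ov <- vapply(truth_labels, function(k) {
    sum(pred_mask == pred_label & truth_mask == k)
  }, numeric(1))
  k <- truth_labels[which.max(ov)]
  2 * max(ov) / (sum(pred_mask == pred_label) + sum(truth_mask == k))
}

quiet_spectrum <- function(series, params = superlet_params(), rate = 1) {
  suppressWarnings(time_avg_spectrum(
    superlet_spectrogram(series, params, rate)))
}
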