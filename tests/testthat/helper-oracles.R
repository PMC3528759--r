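# Independent brute-force oracles, implemented deliberately without reusing
# the package's internals.

# shoelace signed area by explicit loop
oracle_shoelace <- function(xy) {
  n <- nrow(xy); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + xy[i, 1L] * xy[j, 2L] - xy[j, 1L] * xy[i, 2L]
  }
  s / 2
}

# one Laplacian smoothing iteration by explicit per-vertex averaging
oracle_smooth_once <- function(xy, lambda) {
  n <- nrow(xy)
  out <- xy
  for (i in seq_len(n)) {
    p <- if (i == 1L) n else i - 1L
    q <- if (i == n) 1L else i + 1L
    out[i, ] <- xy[i, ] + lambda * ((xy[p, ] + xy[q, ]) / 2 - xy[i, ])
  }
  out
}

# explicit per-pixel flow summation (mL/s)
oracle_roi_flow <- function(field, roi, phase) {
  s <- 0
  for (i in seq_len(nrow(roi$mask))) {
    for (j in seq_len(ncol(roi$mask))) {
      if (roi$mask[i, j]) {
        s <- s + field$components$z[i, j, roi$z_index, phase] *
          roi$pixel_area
      }
    }
  }
  s * 10 / 1000
}

# periodic trapezoid mean via explicit segment sums
oracle_cycle_mean <- function(q) {
  n <- length(q); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + (q[i] + q[j]) / 2
  }
  s / n
}

# intensity-weighted centroid of (image - background)
oracle_centroid <- function(img, xs, ys, background) {
  w <- pmax(img - background, 0)
  c(sum(outer(xs, rep(1, length(ys))) * w),
    sum(outer(rep(1, length(xs)), ys) * w)) / sum(w)
}

# max-relative-error by explicit loop over probe points
oracle_max_rel_err <- function(vf, vc) {
  num <- 0; den <- 0
  for (i in seq_along(vf)) {
    num <- max(num, abs(vf[i] - vc[i]))
    den <- max(den, abs(vf[i]))
  }
  100 * num / den
}

# two-pass mean / sd
oracle_mean_sd <- function(v) {
  m <- sum(v) / length(v)
  s <- if (length(v) > 1) sqrt(sum((v - m)^2) / (length(v) - 1)) else 0
  c(mean = m, sd = s)
}
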