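# Shared fixture builders. Everything is generated in code; no binary files.

# A straight horizontal test cell.
straight_params <- function(a0 = 5, xl = 1, xr = 9, r = 2) {
  coord_params(a0 = a0, a1 = 0, a2 = 0, xl = xl, xr = xr, r = r)
}

# A gently curved cell, comfortably inside a 20 x 34 frame.
curved_params <- function() {
  coord_params(a0 = 10, a1 = 0.1, a2 = 0.01, xl = 2, xr = 30, r = 4)
}

# Random valid parameter sets for property-style loops.
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    xl <- runif(1, 0, 10)
    coord_params(
      a0 = runif(1, 5, 30),
      a1 = runif(1, -0.4, 0.4),
      a2 = runif(1, -0.02, 0.02),
      xl = xl,
      xr = xl + runif(1, 8, 40),
      r = runif(1, 2, 7))
  })
}

# Brute-force closest-point oracle: grid search plus parabolic refinement.
brute_closest <- function(params, xp, yp, lo = -50, hi = 80, step = 1e-4) {
  coarse <- seq(lo, hi, by = 0.05)
  d2 <- (coarse - xp)^2 + (midline_y(params, coarse) - yp)^2
  x0 <- coarse[which.min(d2)]
  fine <- seq(x0 - 0.1, x0 + 0.1, by = step)
  d2 <- (fine - xp)^2 + (midline_y(params, fine) - yp)^2
  i <- which.min(d2)
  x <- fine[i]
  if (i > 1 && i < length(fine)) {
    # local parabolic refinement
    y1 <- d2[i - 1]; y2 <- d2[i]; y3 <- d2[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den > 0) x <- x + step * (y1 - y3) / (2 * den)
  }
  min(max(x, params$xl), params$xr)
}

# Render a binary matrix directly from rc <= r (independent of synthetic.R
# internals for use as an oracle).
render_mask_oracle <- function(params, dim) {
  (coordinate_maps(params, dim)$rc <= params$r) * 1
}
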