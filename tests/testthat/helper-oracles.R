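# Shared fixtures and independent oracles used across the test files.

# small, fast scene for contract tests
tiny_scene <- function(display = "CONTINUOUS_RAPID_GL",
                       habitat = "CLUMPED_LOWGAIN_CF",
                       wind_level = 4, seed = 9, duration = 1.2,
                       width = 64, height = 48, ...) {
  generate_scene(scene_spec(display, habitat, wind_level, seed,
                            width = width, height = height,
                            duration = duration, ...))
}

# brute-force strict-exceedance proportions
oracle_sweep <- function(series, grid) {
  vapply(grid, function(tau) {
    hits <- 0L
    for (v in series) if (v > tau) hits <- hits + 1L
    hits / length(series)
  }, numeric(1))
}

# dense eigen-solution of the stationary distribution of the activation chain
oracle_activation <- function(feature, sigma, eps = 1e-8) {
  n <- length(feature)
  idx <- arrayInd(seq_len(n), dim(feature))
  D2 <- as.matrix(stats::dist(idx))^2
  F <- if (is.finite(sigma)) exp(-D2 / (2 * sigma^2)) else matrix(1, n, n)
  L <- log(as.vector(feature) + eps)
  W <- abs(outer(L, L, `-`)) * F
  d <- rowSums(W)
  P <- W / ifelse(d > 0, d, 1)
  P[d == 0, ] <- 1 / n
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v <- v / sum(v)
  matrix(v, nrow(feature), ncol(feature))
}

# plain-R replicate-padded correlation, independent of the compiled path
oracle_conv2 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(k); kw <- ncol(k)
  cy <- kh %/% 2; cx <- kw %/% 2
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    s <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      yy <- min(max(y + i - 1 - cy, 1), h)
      xx <- min(max(x + j - 1 - cx, 1), w)
      s <- s + img[yy, xx] * k[i, j]
    }
    out[y, x] <- s
  }
  out
}

# gradient-detector support oracle: cells whose luminance changed and whose
# local spatial gradient is resolvable (independent reimplementation)
oracle_motion_support <- function(f1, f2, floor = 1e-3) {
  It <- f2 - f1
  m <- (f1 + f2) / 2
  h <- nrow(m); w <- ncol(m)
  Ix <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  Iy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  abs(It) > 0 & sqrt(Ix^2 + Iy^2) > floor
}

# horizontal/vertical sinusoidal gratings
grating <- function(n = 64, wavelength = 4, vertical = FALSE, shift = 0) {
  idx <- if (vertical) matrix(seq_len(n), n, n, byrow = TRUE)
         else matrix(seq_len(n), n, n)
  0.5 + 0.4 * sin(2 * pi * (idx - shift) / wavelength)
}
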