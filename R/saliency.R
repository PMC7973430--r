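#' Quadrature Gabor filter bank
#'
#' Builds the even/odd (cosine/sine phase) Gabor kernel pair for each of the
#' four stripe orientations 0, 45, 90 and 135 degrees. Kernels are forced to
#' zero mean so constant images give exactly zero response. The same kernels
#' are used at every pyramid level: scale selectivity comes from the dyadic
#' pyramid, not from rescaled filters.
#'
#' @param wavelength carrier wavelength in pixels.
#' @param sigma Gaussian envelope scale in pixels.
#' @return list with `cos` and `sin` kernel lists (one matrix per
#'   orientation), `angles` (stripe orientations, degrees), and `dirs`, an
#'   integer matrix of unit pixel steps `(dx, dy)` along each orientation's
#'   direction of motion sensitivity (orthogonal to the stripes).
#' @export
gabor_bank <- function(wavelength = 4, sigma = 2) {
  angles <- c(0, 45, 90, 135)
  r <- as.integer(ceiling(2.5 * sigma))
  xs <- -r:r
  G <- outer(exp(-xs^2 / (2 * sigma^2)), exp(-xs^2 / (2 * sigma^2)))
  cosk <- sink <- vector("list", length(angles))
  dirs <- matrix(0L, length(angles), 2, dimnames = list(NULL, c("dx", "dy")))
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    # stripes at angle `th` from horizontal: carrier varies along (-sin, cos)
    phase <- outer(xs * cos(th), xs * (-sin(th)), `+`) * (2 * pi / wavelength)
    ce <- G * cos(phase); ce <- ce - mean(ce)
    se <- G * sin(phase); se <- se - mean(se)
    cosk[[i]] <- ce; sink[[i]] <- se
    dirs[i, ] <- as.integer(round(c(-sin(th), cos(th))))
  }
  list(cos = cosk, sin = sink, angles = angles, dirs = dirs,
       support = 2L * r + 1L)
}

pyramid_level_dims <- function(h, w, n_levels = 9) {
  out <- matrix(0L, n_levels, 2)
  for (k in seq_len(n_levels)) {
    out[k, ] <- as.integer(c(h, w))
    h <- ceiling(h / 2); w <- ceiling(w / 2)
  }
  out
}

#' Oriented Gabor pyramid of one frame
#'
#' Dyadic low-pass pyramid (binomial kernel, factor-2 subsampling, nine
#' levels: sampling ratios 1:1 down to 1:256) with quadrature Gabor response
#' magnitudes at four orientations per level.
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param bank filter bank from [gabor_bank()].
#' @param n_levels number of pyramid levels (default 9).
#' @return object of class `gabor_pyramid`: `resp[[orientation]][[level]]`
#'   response-magnitude matrices, plus the bank and level geometry.
#' @export
gabor_pyramid <- function(frame, bank = gabor_bank(), n_levels = 9) {
  if (!is.matrix(frame) || anyNA(frame) || min(frame) < 0 || max(frame) > 1)
    stop("frame must be a numeric matrix with values in [0, 1]")
  if (min(dim(frame)) < bank$support)
    stop(sprintf("frame smaller than filter support (%d px) at level 1",
                 bank$support))
  imgs <- vector("list", n_levels)
  imgs[[1]] <- frame
  for (k in seq_len(n_levels - 1) + 1) imgs[[k]] <- cpp_decimate2(imgs[[k - 1]])
  resp <- lapply(seq_along(bank$angles), function(o) {
    lapply(imgs, function(im) {
      ce <- cpp_conv2(im, bank$cos[[o]])
      se <- cpp_conv2(im, bank$sin[[o]])
      sqrt(ce^2 + se^2)
    })
  })
  structure(list(resp = resp, bank = bank, n_levels = n_levels,
                 dim = dim(frame)),
            class = "gabor_pyramid")
}

#' Opponent Reichardt correlation of two response maps
#'
#' The elementary motion detector: `R(x) = prev(x) * curr(x + d) -
#' curr(x) * prev(x + d)` for a pixel shift `d = (dx, dy)`; cells whose
#' shifted partner falls outside the array are 0.
#'
#' @param prev,curr same-size numeric matrices (responses of consecutive
#'   frames).
#' @param dx,dy integer shift in columns/rows.
#' @param signed if `FALSE` (default) return `|R|`; if `TRUE` the signed
#'   opponent response (positive for motion along `+d`).
#' @return matrix of the same size.
#' @export
reichardt_pair <- function(prev, curr, dx, dy, signed = FALSE) {
  if (!identical(dim(prev), dim(curr)))
    stop("response maps must have identical shape")
  cpp_reichardt(prev, curr, as.integer(dx), as.integer(dy), isTRUE(signed))
}

#' Reichardt motion pyramid from two Gabor pyramids
#'
#' Applies [reichardt_pair()] at every orientation and level, shifting by
#' `shift` pixels along each orientation's direction of motion sensitivity,
#' and returns response magnitudes.
#'
#' @param prev,curr [gabor_pyramid()]s of consecutive frames with identical
#'   geometry.
#' @param shift shift in pixels (default 1).
#' @return object of class `motion_pyramid` with `resp[[orientation]][[level]]`
#'   non-negative matrices.
#' @export
reichardt_motion <- function(prev, curr, shift = 1) {
  stopifnot(inherits(prev, "gabor_pyramid"), inherits(curr, "gabor_pyramid"))
  if (!identical(prev$dim, curr$dim) || prev$n_levels != curr$n_levels)
    stop("pyramids must have identical geometry")
  dirs <- prev$bank$dirs
  resp <- lapply(seq_along(prev$resp), function(o) {
    d <- dirs[o, ] * as.integer(shift)
    lapply(seq_len(prev$n_levels), function(k)
      cpp_reichardt(prev$resp[[o]][[k]], curr$resp[[o]][[k]], d[1], d[2], FALSE))
  })
  structure(list(resp = resp, dirs = dirs, shift = shift,
                 n_levels = prev$n_levels, dim = prev$dim),
            class = "motion_pyramid")
}

#' Graph-based saliency activation
#'
#' Markov-chain activation of a non-negative feature map: a fully connected
#' directed graph over cells with edge weight
#' `w(i -> j) = |log((f_i + eps) / (f_j + eps))| * exp(-d^2(i, j) / (2 sigma^2))`,
#' row-normalised into a transition matrix whose stationary distribution
#' (power iteration) is returned as a map summing to 1. Mass accumulates on
#' cells that differ from their surround. Degenerate inputs (all-zero or
#' uniform maps, whose dissimilarities all vanish) yield the uniform map.
#'
#' @param feature non-negative numeric matrix with >= 2 cells.
#' @param sigma distance falloff scale in cells (`Inf` disables the falloff).
#' @param eps log-dissimilarity regulariser.
#' @param tol L1 convergence tolerance (used by the `"power"` solver).
#' @param maxit maximum iterations (used by the `"power"` solver).
#' @param method `"direct"` solves the stationary system exactly by dense
#'   elimination (default); `"power"` uses damped power iteration to `tol`.
#'   Both converge to the same distribution; the direct solver is also total
#'   on periodic chains.
#' @return matrix of the same shape, non-negative, summing to 1.
#' @export
gbvs_activation <- function(feature, sigma = 3, eps = 1e-8, tol = 1e-9,
                            maxit = 10000, method = c("direct", "power")) {
  method <- match.arg(method)
  if (!is.matrix(feature) || length(feature) < 2)
    stop("feature must be a matrix with >= 2 cells")
  if (anyNA(feature) || min(feature) < 0)
    stop("feature values must be non-negative")
  F <- cpp_dist_kernel(nrow(feature), ncol(feature), sigma)
  cpp_gbvs_activation(feature, F, eps, tol, maxit,
                      if (method == "power") 1L else 0L)
}

#' Graph-based saliency normalisation
#'
#' Second Markov chain concentrating mass on high-activation cells:
#' `w(i -> j) = a_j * exp(-d^2(i, j) / (2 sigma^2))` (self-edges included),
#' returning the stationary distribution.
#'
#' @param activation matrix summing to 1 (an activation map).
#' @inheritParams gbvs_activation
#' @return matrix of the same shape summing to 1.
#' @export
gbvs_normalize <- function(activation, sigma = 3, tol = 1e-9, maxit = 10000,
                           method = c("direct", "power")) {
  method <- match.arg(method)
  if (!is.matrix(activation) || length(activation) < 2)
    stop("activation must be a matrix with >= 2 cells")
  if (abs(sum(activation) - 1) > 1e-6)
    stop("activation must sum to 1")
  F <- cpp_dist_kernel(nrow(activation), ncol(activation), sigma)
  cpp_gbvs_normalize(activation, F, tol, maxit,
                     if (method == "power") 1L else 0L)
}

#' Saliency model parameters
#'
#' @param n_levels pyramid levels (9: sampling ratios 1:1 to 1:256).
#' @param wavelength,sigma_gabor Gabor carrier wavelength and envelope scale
#'   (px).
#' @param shift Reichardt shift in pixels.
#' @param cell_px working-grid cell size: the graph stage runs on the frame
#'   downscaled by this factor, clamped to at most 32 x 24 (and at least
#'   2 x 2) cells to keep the fully connected chain tractable.
#' @param sigma_graph distance falloff (working cells) for both graph passes;
#'   the default keeps sigma at 1/8 of the working-grid width, the
#'   conventional relative falloff of graph-based saliency maps (3 cells on a
#'   24-cell-wide grid, 1.5 on the default 12-cell grid).
#' @param eps log-dissimilarity regulariser.
#' @param tol,maxit power-iteration stopping rule.
#' @param normalize `"frame"` rescales each map by its own maximum;
#'   `"sequence"` rescales all maps by the global maximum.
#' @return list of parameters for [saliency_map()].
#' @export
saliency_params <- function(n_levels = 9, wavelength = 4, sigma_gabor = 2,
                            shift = 1, cell_px = 8, sigma_graph = 1.5,
                            eps = 1e-8, tol = 1e-9, maxit = 10000,
                            normalize = c("frame", "sequence")) {
  list(n_levels = as.integer(n_levels), wavelength = wavelength,
       sigma_gabor = sigma_gabor, shift = as.integer(shift),
       cell_px = cell_px, sigma_graph = sigma_graph, eps = eps, tol = tol,
       maxit = as.integer(maxit), normalize = match.arg(normalize))
}

working_dims <- function(h, w, cell_px) {
  c(clamp(round(h / cell_px), 2, 24), clamp(round(w / cell_px), 2, 32))
}

#' Motion-channel saliency maps of an image sequence
#'
#' The full motion channel: per frame pair, oriented Gabor pyramids of both
#' frames feed opponent Reichardt correlation (both directions, magnitudes
#' summed) at every orientation and level; each motion map is resampled to a
#' common working resolution and passed through the graph-based activation
#' chain; activations are summed across orientations and levels, passed
#' through the normalisation chain, upsampled to frame resolution and
#' rescaled to `[0, 1]`. Frame pairs with no motion energy anywhere yield
#' identically zero maps, and all-zero orientation/level maps contribute
#' nothing to the sum.
#'
#' @param seq an [image_sequence()] (length >= 2).
#' @param params from [saliency_params()].
#' @return object of class `saliency_sequence`: `maps` (one per frame pair,
#'   frame resolution, values in `[0, 1]`, per-map maximum 1 unless
#'   identically zero under `"frame"` normalisation) and `fps`.
#' @export
saliency_map <- function(seq, params = saliency_params()) {
  seq <- as_image_sequence(seq)
  if (length(seq$frames) < 2) stop("need >= 2 frames")
  bank <- gabor_bank(params$wavelength, params$sigma_gabor)
  d <- frame_dim(seq)
  if (min(d) < bank$support)
    stop(sprintf("frame smaller than filter support (%d px) at level 1",
                 bank$support))
  wd <- working_dims(d[1], d[2], params$cell_px)
  F <- cpp_dist_kernel(wd[1], wd[2], params$sigma_graph)
  raw <- cpp_saliency_sequence(seq$frames, bank$cos, bank$sin, bank$dirs,
                               params$n_levels, wd[1], wd[2], F, params$eps,
                               params$tol, params$maxit, params$shift)
  if (params$normalize == "frame") {
    maps <- lapply(raw, function(m) { mx <- max(m); if (mx > 0) m / mx else m })
  } else {
    mx <- max(vapply(raw, max, numeric(1)))
    maps <- if (mx > 0) lapply(raw, function(m) m / mx) else raw
  }
  structure(list(maps = maps, fps = seq$fps, working_dims = wd,
                 params = params),
            class = "saliency_sequence")
}

#' Resample a map to a target shape
#'
#' Box-average when shrinking, bilinear when enlarging; used to move feature
#' maps to and from the graph stage's working resolution.
#'
#' @param m numeric matrix.
#' @param h,w target shape.
#' @return `h x w` matrix.
#' @export
resize_map <- function(m, h, w) cpp_resize(m, as.integer(h), as.integer(w))
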