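central_diff_x <- function(m) {
  w <- ncol(m)
  left <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  (right - left) / 2
}

central_diff_y <- function(m) {
  h <- nrow(m)
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  down <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  (down - up) / 2
}

#' Gradient-detector motion analysis
#'
#' Computes per-frame-pair motion magnitude maps from spatial and temporal
#' luminance derivatives of (optionally Gaussian-smoothed) frames. The
#' magnitude is the normal-flow speed `|dI/dt| / (|grad I| + eps)` wherever
#' the spatial gradient magnitude exceeds a floor, and 0 elsewhere — so a
#' cell is non-zero iff its luminance changed between the two frames *and*
#' local structure makes that change resolvable (a global brightness step
#' over a flat region is suppressed). Frame-pair maps attach to the later
#' frame.
#'
#' @param seq an [image_sequence()] (length >= 2).
#' @param smoothing Gaussian smoothing scale in pixels (0 disables).
#' @param threshold magnitudes strictly below this are set to 0 (default 0:
#'   strict non-zero).
#' @param grid_factor integer pixel-to-cell downscale of the analysis grid
#'   (cells aggregate by averaging; a cell is non-zero iff any member pixel
#'   is).
#' @param gradient_floor minimum spatial gradient magnitude (luminance/px)
#'   for motion to be resolvable.
#' @param eps regulariser in the normal-flow denominator.
#' @return object of class `motion_map_sequence`: list with `maps` (length
#'   `frames - 1`, values >= 0) and `grid_factor`.
#' @export
detect_motion <- function(seq, smoothing = 1, threshold = 0, grid_factor = 1,
                          gradient_floor = 1e-3, eps = 1e-6) {
  seq <- as_image_sequence(seq)
  if (length(seq$frames) < 2) stop("need >= 2 frames")
  frames <- seq$frames
  if (smoothing > 0) {
    k <- gaussian_kernel2d(smoothing)
    frames <- lapply(frames, cpp_conv2, kernel = k)
  }
  n <- length(frames)
  maps <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    f1 <- frames[[i]]; f2 <- frames[[i + 1]]
    It <- f2 - f1
    m <- (f1 + f2) / 2
    gmag <- sqrt(central_diff_x(m)^2 + central_diff_y(m)^2)
    mag <- ifelse(gmag > gradient_floor, abs(It) / (gmag + eps), 0)
    mag[mag < threshold] <- 0
    if (grid_factor > 1)
      mag <- cpp_resize(mag, ceiling(nrow(mag) / grid_factor),
                        ceiling(ncol(mag) / grid_factor))
    maps[[i]] <- mag
  }
  structure(list(maps = maps, grid_factor = as.integer(grid_factor)),
            class = "motion_map_sequence")
}

#' Spatial extent of movement per frame pair
#'
#' Counts the strictly positive cells of each motion map: the temporal
#' structure profile of a sequence.
#'
#' @param mm a `motion_map_sequence` from [detect_motion()].
#' @return integer vector of per-frame-pair non-zero cell counts.
#' @export
motion_extent <- function(mm) {
  stopifnot(inherits(mm, "motion_map_sequence"))
  vapply(mm$maps, function(m) sum(m > 0), integer(1))
}

# 3x3 (8-neighbour) binary dilation, `times` passes
dilate_binary <- function(m, times = 1) {
  h <- nrow(m); w <- ncol(m)
  for (k in seq_len(times)) {
    p <- matrix(0, h + 2, w + 2)
    p[2:(h + 1), 2:(w + 1)] <- m
    out <- matrix(0, h, w)
    for (dr in 0:2) for (dc in 0:2)
      out <- pmax(out, p[seq_len(h) + dr, seq_len(w) + dc, drop = FALSE])
    m <- out
  }
  m
}

#' Binary signaller mask from a baseline sequence
#'
#' Runs [detect_motion()] on the baseline (signal-only) sequence and converts
#' all non-zero cells to 1, optionally dilating the mask to guard against
#' 1-px misregistration between the baseline and the composite.
#'
#' @inheritParams detect_motion
#' @param baseline the baseline [image_sequence()].
#' @param dilate number of 1-cell dilation passes (0 = strict mask).
#' @return object of class `mask_sequence`: list with `masks` (binary 0/1
#'   matrices, one per frame pair) and `grid_factor`.
#' @export
signal_mask <- function(baseline, smoothing = 1, threshold = 0, dilate = 1,
                        grid_factor = 1) {
  mm <- detect_motion(baseline, smoothing = smoothing, threshold = threshold,
                      grid_factor = grid_factor)
  masks <- lapply(mm$maps, function(m) {
    b <- (m > 0) * 1
    if (dilate > 0) b <- dilate_binary(b, dilate)
    b
  })
  structure(list(masks = masks, grid_factor = mm$grid_factor),
            class = "mask_sequence")
}
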