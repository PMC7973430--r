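#' Receiver-threshold grid
#'
#' The default grid is 1000 ascending thresholds 0.001, 0.002, ..., 1.000;
#' `n = 100` gives the coarser 0.01-increment alternative.
#'
#' @param n number of thresholds.
#' @return ascending numeric vector in `(0, 1]`.
#' @export
threshold_grid <- function(n = 1000) seq_len(n) / n

#' Receiver-threshold categories
#'
#' Low `[0, 0.3)`, moderate `[0.3, 0.8)` and high `[0.8, 1]` threshold bands;
#' boundary thresholds are assigned upward (0.3 is moderate, 0.8 is high).
#'
#' @return named list of `(lower, upper)` bounds partitioning `[0, 1]`.
#' @export
threshold_categories <- function() {
  list(low = c(0, 0.3), moderate = c(0.3, 0.8), high = c(0.8, 1))
}

#' Per-frame maximum salience within the signaller mask
#'
#' Multiplies each saliency map by the corresponding binary signaller mask
#' and takes the per-frame-pair maximum: the relative salience of the
#' signaller's movements in context. Masks on a coarser analysis grid are
#' resampled to frame resolution first (any positive coverage counts).
#'
#' @param sal a `saliency_sequence` from [saliency_map()].
#' @param masks a `mask_sequence` from [signal_mask()] of the same length.
#' @return numeric vector in `[0, 1]`, one value per frame pair.
#' @export
masked_salience <- function(sal, masks) {
  stopifnot(inherits(sal, "saliency_sequence"), inherits(masks, "mask_sequence"))
  if (length(sal$maps) != length(masks$masks))
    stop("saliency and mask sequences differ in length")
  vapply(seq_along(sal$maps), function(i) {
    m <- masks$masks[[i]]
    if (!identical(dim(m), dim(sal$maps[[i]])))
      m <- (cpp_resize(m, nrow(sal$maps[[i]]), ncol(sal$maps[[i]])) > 0) * 1
    max(sal$maps[[i]] * m)
  }, numeric(1))
}

#' Receiver-threshold performance vector
#'
#' For each threshold on the grid, the proportion of the sequence whose
#' masked salience strictly exceeds it.
#'
#' @param series numeric salience series in `[0, 1]` (from
#'   [masked_salience()]).
#' @param grid ascending thresholds in `(0, 1]` (default
#'   [threshold_grid()]).
#' @return object of class `performance_vector`: list with `thresholds` and
#'   `proportions` (non-increasing, in `[0, 1]`).
#' @export
threshold_sweep <- function(series, grid = threshold_grid()) {
  if (length(series) == 0) stop("empty salience series")
  if (anyNA(series)) stop("salience series contains NA")
  if (is.unsorted(grid, strictly = TRUE) || min(grid) <= 0 || max(grid) > 1)
    stop("grid must be strictly ascending within (0, 1]")
  s <- sort(series)
  n <- length(s)
  # findInterval counts elements <= tau, so n minus it is the strict count
  p <- (n - findInterval(grid, s)) / n
  structure(list(thresholds = grid, proportions = p),
            class = "performance_vector")
}

#' Mean performance per receiver-threshold category
#'
#' Averages a performance vector's proportions within the low, moderate and
#' high threshold categories.
#'
#' @param pv a [threshold_sweep()] result.
#' @param cats category bounds, default [threshold_categories()].
#' @return named numeric vector `c(low = , moderate = , high = )`.
#' @export
categorize <- function(pv, cats = threshold_categories()) {
  stopifnot(inherits(pv, "performance_vector"))
  tau <- pv$thresholds
  bin <- ifelse(tau < cats$low[2], "low",
                ifelse(tau < cats$moderate[2], "moderate", "high"))
  out <- vapply(c("low", "moderate", "high"),
                function(b) mean(pv$proportions[bin == b]), numeric(1))
  names(out) <- c("low", "moderate", "high")
  out
}
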