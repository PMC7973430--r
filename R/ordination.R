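#' Dissimilarity matrix between performance vectors
#'
#' Bray-Curtis (default) or Euclidean dissimilarities between performance
#' vectors sharing one threshold grid. Bray-Curtis between two all-zero
#' vectors is defined as 0 (identical vectors).
#'
#' @param vectors list of `performance_vector`s on one grid.
#' @param metric `"bray"` or `"euclidean"`.
#' @return symmetric matrix with zero diagonal and a `metric` attribute.
#' @export
dissimilarity_matrix <- function(vectors, metric = c("bray", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(length(vectors) >= 2,
            all(vapply(vectors, inherits, logical(1), "performance_vector")))
  grid <- vectors[[1]]$thresholds
  for (v in vectors)
    if (!isTRUE(all.equal(v$thresholds, grid)))
      stop("all performance vectors must share one threshold grid")
  m <- do.call(rbind, lapply(vectors, `[[`, "proportions"))
  d <- as.matrix(vegan::vegdist(m, method = metric))
  d[is.nan(d)] <- 0
  dimnames(d) <- NULL
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Wraps `vegan::metaMDS` (global NMDS by iterative Kruskal stress-1
#' minimisation with monotone regression, best of `n_starts` random starts).
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimensions (default 2).
#' @param seed integer seed for the random starts.
#' @param n_starts number of random starts.
#' @param maxit iterations per start.
#' @return object of class `ordination_result`: `coordinates` (one row per
#'   object), `stress` (Kruskal stress-1, as a fraction), `converged`,
#'   `degenerate` (all-zero input), and `seed`.
#' @export
nmds <- function(d, k = 2, seed = 1, n_starts = 20, maxit = 500) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), k >= 1)
  if (max(d) == 0) {
    return(structure(list(coordinates = matrix(0, nrow(d), k), stress = 0,
                          converged = FALSE, degenerate = TRUE,
                          seed = as.integer(seed)),
                     class = "ordination_result"))
  }
  fit <- withr::with_seed(as.integer(seed),
    vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts, maxit = maxit,
                   trace = 0, smin = 1e-9, sfgrmin = 1e-9,
                   sratmax = 0.9999999))
  structure(list(coordinates = unname(fit$points), stress = fit$stress,
                 converged = isTRUE(fit$converged) || is.numeric(fit$converged) &&
                   fit$converged > 0,
                 degenerate = FALSE, seed = as.integer(seed)),
            class = "ordination_result")
}

#' Mean within-group pairwise distance of ordination points
#'
#' @param coordinates numeric matrix of embedded points (rows).
#' @param groups group label per point.
#' @return named numeric vector of mean pairwise distances; `NA` for
#'   singleton groups.
#' @export
cluster_tightness <- function(coordinates, groups) {
  coordinates <- as.matrix(coordinates)
  stopifnot(nrow(coordinates) == length(groups))
  levs <- unique(groups)
  out <- vapply(levs, function(g) {
    pts <- coordinates[groups == g, , drop = FALSE]
    if (nrow(pts) < 2) return(NA_real_)
    mean(stats::dist(pts))
  }, numeric(1))
  names(out) <- as.character(levs)
  out
}
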