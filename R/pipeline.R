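#' Experiment configuration
#'
#' Defaults reproduce the study design at desk scale: all four display
#' archetypes crossed with all four habitat archetypes under wind levels
#' 1..10 (160 cells), 96 x 72 px frames, 8 s at 25 fps. Scene seeds are
#' derived from the master seed by a stable hash of (display, habitat) so
#' that wind acts as a pure controller on a fixed scene layout and the
#' baseline is shared across wind levels, one per display-habitat
#' combination.
#'
#' @param displays,habitats,wind_levels factor levels of the design.
#' @param seed master seed.
#' @param width,height,fps,duration scene geometry.
#' @param motion list of [detect_motion()] / [signal_mask()] parameters.
#' @param saliency [saliency_params()].
#' @param grid receiver-threshold grid.
#' @param out_dir optional artifact directory enabling resumable runs.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(displays = DISPLAY_ARCHETYPES,
                              habitats = HABITAT_ARCHETYPES,
                              wind_levels = 1:10, seed = 1,
                              width = 96, height = 72, fps = 25, duration = 8,
                              motion = list(smoothing = 1, threshold = 0,
                                            dilate = 1),
                              saliency = saliency_params(),
                              grid = threshold_grid(),
                              out_dir = NULL) {
  stopifnot(length(displays) >= 1, length(habitats) >= 1,
            length(wind_levels) >= 1,
            all(displays %in% DISPLAY_ARCHETYPES),
            all(habitats %in% HABITAT_ARCHETYPES),
            all(wind_levels %in% 1:10))
  structure(list(displays = displays, habitats = habitats,
                 wind_levels = as.integer(wind_levels),
                 seed = as.integer(seed), width = width, height = height,
                 fps = fps, duration = duration, motion = motion,
                 saliency = saliency, grid = grid, out_dir = out_dir),
            class = "experiment_config")
}

config_hash <- function(cfg) {
  key <- cfg[c("displays", "habitats", "wind_levels", "seed", "width",
               "height", "fps", "duration", "motion", "saliency")]
  stable_hash(paste(deparse(key), collapse = ""), length(cfg$grid))
}

#' Enumerate the factorial cells of a configuration
#'
#' @param cfg an [experiment_config()].
#' @return tibble with one row per (display, habitat, wind_level) cell and
#'   its derived scene seed.
#' @export
factorial_cells <- function(cfg) {
  g <- expand.grid(wind_level = cfg$wind_levels, habitat = cfg$habitats,
                   display = cfg$displays, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("display", "habitat", "wind_level")]
  g$scene_seed <- mapply(function(d, h) stable_hash(d, h, init = cfg$seed),
                         g$display, g$habitat)
  tibble::as_tibble(g)
}

cell_stub <- function(display, habitat, wind_level)
  sprintf("%s__%s__w%02d", display, habitat, wind_level)

read_cell_artifact <- function(out_dir, stub, hash, grid) {
  side <- file.path(out_dir, paste0(stub, ".json"))
  csv <- file.path(out_dir, paste0(stub, ".csv"))
  if (!file.exists(side) || !file.exists(csv)) return(NULL)
  meta <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta) || !identical(as.integer(meta$config_hash), as.integer(hash)))
    return(NULL)
  tab <- utils::read.csv(csv)
  if (!isTRUE(all.equal(tab$threshold, grid))) return(NULL)
  structure(list(thresholds = grid, proportions = tab$proportion),
            class = "performance_vector")
}

write_cell_artifact <- function(out_dir, stub, hash, spec, pv, cats) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # %.17g keeps the doubles exact across the text round-trip
  utils::write.csv(data.frame(threshold = sprintf("%.17g", pv$thresholds),
                              proportion = sprintf("%.17g", pv$proportions)),
                   file.path(out_dir, paste0(stub, ".csv")), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(config_hash = hash, spec = unclass(spec),
                            categories = as.list(cats)),
                       file.path(out_dir, paste0(stub, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full factorial experiment
#'
#' For every (display, habitat, wind level) cell: generate the scene pair,
#' derive the signaller mask from the baseline, compute motion-channel
#' saliency of the composite, extract the masked salience series, sweep
#' receiver thresholds and summarise by category. Masks are computed once per
#' display-habitat combination (the baseline does not depend on wind). Fully
#' deterministic given the configuration; with `out_dir` set, finished cells
#' are reloaded instead of recomputed.
#'
#' @param cfg an [experiment_config()].
#' @param quiet suppress per-cell progress messages.
#' @return tibble with one row per cell (`display`, `habitat`, `wind_level`,
#'   `scene_seed`, `low`, `moderate`, `high`, `computed`); the performance
#'   vectors are attached as attribute `"vectors"` and the number of freshly
#'   computed cells as attribute `"n_computed"`. Failed cells are reported
#'   via warnings and carry `NA` summaries.
#' @export
run_factorial <- function(cfg, quiet = TRUE) {
  cells <- factorial_cells(cfg)
  hash <- config_hash(cfg)
  mask_cache <- new.env(parent = emptyenv())
  vectors <- vector("list", nrow(cells))
  out <- cells
  out$low <- out$moderate <- out$high <- NA_real_
  out$computed <- FALSE
  n_computed <- 0L
  failed <- character(0)

  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    stub <- cell_stub(row$display, row$habitat, row$wind_level)
    pv <- NULL
    if (!is.null(cfg$out_dir))
      pv <- read_cell_artifact(cfg$out_dir, stub, hash, cfg$grid)
    if (is.null(pv)) {
      res <- tryCatch({
        spec <- scene_spec(row$display, row$habitat, row$wind_level,
                           row$scene_seed, width = cfg$width,
                           height = cfg$height, fps = cfg$fps,
                           duration = cfg$duration)
        pair <- generate_scene(spec)
        key <- paste(row$display, row$habitat, sep = "|")
        masks <- mask_cache[[key]]
        if (is.null(masks)) {
          masks <- signal_mask(pair$baseline,
                               smoothing = cfg$motion$smoothing,
                               threshold = cfg$motion$threshold,
                               dilate = cfg$motion$dilate)
          mask_cache[[key]] <- masks
        }
        sal <- saliency_map(pair$composite, cfg$saliency)
        series <- masked_salience(sal, masks)
        pv <- threshold_sweep(series, cfg$grid)
        cats <- categorize(pv)
        if (!is.null(cfg$out_dir))
          write_cell_artifact(cfg$out_dir, stub, hash, spec, pv, cats)
        list(pv = pv, cats = cats)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, sprintf("%s: %s", stub, conditionMessage(res)))
        next
      }
      pv <- res$pv
      out$computed[i] <- TRUE
      n_computed <- n_computed + 1L
      if (!quiet) message(sprintf("[%3d/%d] %s", i, nrow(cells), stub))
    }
    cats <- categorize(pv)
    vectors[[i]] <- pv
    out$low[i] <- cats[["low"]]
    out$moderate[i] <- cats[["moderate"]]
    out$high[i] <- cats[["high"]]
  }
  if (length(failed) > 0)
    warning("failed cells:\n", paste(failed, collapse = "\n"))
  attr(out, "vectors") <- vectors
  attr(out, "n_computed") <- n_computed
  attr(out, "config_hash") <- hash
  out
}

#' Wind band of a wind level
#'
#' Calm (levels 1-3), moderate (4-7) and strong (8-10) wind groupings.
#'
#' @param wind_level integer vector in 1..10.
#' @return factor with levels calm, moderate, strong.
#' @export
wind_band <- function(wind_level) {
  cut(wind_level, breaks = c(0, 3, 7, 10),
      labels = c("calm", "moderate", "strong"))
}

#' Summarise factorial results for one threshold category
#'
#' @param results a [run_factorial()] table.
#' @param category `"low"`, `"moderate"` or `"high"`.
#' @param bands if `TRUE`, group wind levels into calm/moderate/strong bands.
#' @return tidy tibble of mean category performance keyed by display,
#'   habitat and wind level (or band). Cells with missing summaries are
#'   dropped with a warning.
#' @export
summarize_performance <- function(results, category = "moderate",
                                  bands = FALSE) {
  category <- match.arg(category, c("low", "moderate", "high"))
  if (anyNA(results[[category]])) {
    warning("dropping ", sum(is.na(results[[category]])),
            " cells with missing summaries")
    results <- results[!is.na(results[[category]]), ]
  }
  df <- data.frame(display = results$display, habitat = results$habitat,
                   wind = if (bands) wind_band(results$wind_level)
                          else results$wind_level,
                   value = results[[category]])
  agg <- stats::aggregate(value ~ display + habitat + wind, df, mean)
  names(agg)[names(agg) == "wind"] <- if (bands) "wind_band" else "wind_level"
  tibble::as_tibble(agg)
}

#' Ordination of factorial performance vectors
#'
#' Builds the dissimilarity matrix over all performance vectors of a
#' factorial run and embeds them with [nmds()].
#'
#' @param results a [run_factorial()] table.
#' @param metric dissimilarity metric, see [dissimilarity_matrix()].
#' @param k,seed,n_starts passed to [nmds()].
#' @return list with the `ordination_result` (`fit`), the `coordinates`
#'   joined with cell metadata (tibble), and the dissimilarity matrix.
#' @export
ordinate_results <- function(results, metric = "bray", k = 2, seed = 1,
                             n_starts = 20) {
  vectors <- attr(results, "vectors")
  keep <- !vapply(vectors, is.null, logical(1))
  d <- dissimilarity_matrix(vectors[keep], metric = metric)
  fit <- nmds(d, k = k, seed = seed, n_starts = n_starts)
  meta <- results[keep, c("display", "habitat", "wind_level")]
  meta$band <- wind_band(meta$wind_level)
  coords <- cbind(meta, as.data.frame(fit$coordinates))
  names(coords)[seq_len(k) + 4] <- paste0("NMDS", seq_len(k))
  list(fit = fit, coordinates = tibble::as_tibble(coords), dissimilarity = d)
}
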