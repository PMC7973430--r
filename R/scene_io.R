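#' Write a scene pair to disk
#'
#' Writes `composite/` and `baseline/` frame stacks plus a `scene.json`
#' sidecar holding the scene specification and per-frame truth region.
#' `format = "png"` writes one 8-bit PNG per frame; `format = "tiff"` writes
#' one 16-bit multi-page TIFF per sequence.
#'
#' @param pair a `scene_pair` from [generate_scene()].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(pair, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(pair, "scene_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("composite", "baseline")) {
    frames <- pair[[part]]$frames
    if (format == "png") {
      sub <- file.path(dir, part)
      dir.create(sub, showWarnings = FALSE)
      for (i in seq_along(frames))
        png::writePNG(frames[[i]], file.path(sub, sprintf("frame_%04d.png", i)))
    } else {
      tiff::writeTIFF(frames, file.path(dir, paste0(part, ".tiff")),
                      bits.per.sample = 16L)
    }
  }
  jsonlite::write_json(list(spec = unclass(pair$spec), format = format,
                            truth_region = pair$truth_region),
                       file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a scene pair written by [write_scene()]
#'
#' @param dir directory containing the frame stacks and `scene.json`.
#' @return a `scene_pair` (frame values carry the container's quantisation:
#'   8-bit for PNG, 16-bit for TIFF).
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  spec <- do.call(scene_spec, as.list(meta$spec))
  seqs <- lapply(c("composite", "baseline"), function(part) {
    if (identical(meta$format, "tiff")) {
      frames <- tiff::readTIFF(file.path(dir, paste0(part, ".tiff")),
                               all = TRUE)
    } else {
      files <- sort(list.files(file.path(dir, part), pattern = "\\.png$",
                               full.names = TRUE))
      frames <- lapply(files, function(f) {
        m <- png::readPNG(f)
        if (length(dim(m)) == 3) m <- m[, , 1]
        m
      })
    }
    image_sequence(frames, spec$fps)
  })
  truth <- matrix(as.integer(meta$truth_region), ncol = 4,
                  dimnames = list(NULL, c("rmin", "rmax", "cmin", "cmax")))
  structure(list(composite = seqs[[1]], baseline = seqs[[2]],
                 truth_region = truth, spec = spec),
            class = "scene_pair")
}
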