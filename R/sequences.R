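#' Ordered grayscale image sequence
#'
#' The basic container of the package: an ordered list of luminance frames in
#' `[0, 1]`, all of one shape, sampled at a fixed frame rate.
#'
#' @param frames list of numeric matrices with values in `[0, 1]`.
#' @param fps frames per second (positive).
#' @return an object of class `image_sequence` with elements `frames` and `fps`.
#' @export
image_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) < 2)
    stop("an image sequence needs >= 2 frames")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a positive scalar")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !is.numeric(f))
      stop("frames must be numeric matrices")
    if (!identical(dim(f), d))
      stop("all frames must share one shape")
    if (anyNA(f) || min(f) < 0 || max(f) > 1)
      stop("frame values must lie in [0, 1]")
  }
  structure(list(frames = frames, fps = as.numeric(fps)),
            class = "image_sequence")
}

#' @export
length.image_sequence <- function(x) length(x$frames)

frame_dim <- function(seq) dim(seq$frames[[1]])

#' @export
print.image_sequence <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf("<image_sequence: %d frames of %dx%d px @ %g fps>\n",
              length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

as_image_sequence <- function(x, fps = 25) {
  if (inherits(x, "image_sequence")) return(x)
  image_sequence(x, fps)
}
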