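test_that("constant sequences produce all-zero motion maps", {
  frames <- replicate(4, matrix(0.3, 40, 40), simplify = FALSE)
  mm <- detect_motion(image_sequence(frames, 25))
  expect_length(mm$maps, 3)
  for (m in mm$maps) expect_identical(max(m), 0)
  expect_identical(motion_extent(mm), rep(0L, 3))
})

test_that("single-frame sequences are rejected", {
  expect_error(image_sequence(list(matrix(0.5, 40, 40)), 25), ">= 2 frames")
})

test_that("a translating block fires exactly where the frame difference does", {
  mk <- function(col) { m <- matrix(0, 40, 40); m[20:21, col:(col + 1)] <- 1; m }
  frames <- lapply(c(10, 11, 12), mk)
  mm <- detect_motion(image_sequence(frames, 25), smoothing = 0)
  for (i in 1:2) {
    diff_cells <- which(abs(frames[[i + 1]] - frames[[i]]) > 0)
    got_cells <- which(mm$maps[[i]] > 0)
    expect_identical(sort(got_cells), sort(diff_cells))
  }
  # 2 trailing + 2 leading cells per frame pair
  expect_identical(motion_extent(mm), rep(4L, 2))
})

test_that("a global brightness step over a flat field is suppressed", {
  frames <- list(matrix(0.4, 40, 40), matrix(0.6, 40, 40))
  mm <- detect_motion(image_sequence(frames, 25), smoothing = 0)
  expect_identical(max(mm$maps[[1]]), 0)
})

test_that("motion extent is invariant under positive rescaling of magnitudes", {
  p <- tiny_scene(duration = 0.4)
  mm <- detect_motion(p$composite)
  scaled <- mm
  scaled$maps <- lapply(mm$maps, `*`, 37.5)
  expect_identical(motion_extent(scaled), motion_extent(mm))
})

test_that("motion detection commutes with horizontal mirroring", {
  p <- tiny_scene(duration = 0.4)
  mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  mm <- detect_motion(p$composite, smoothing = 1)
  mirrored <- image_sequence(lapply(p$composite$frames, mirror),
                             p$composite$fps)
  mm2 <- detect_motion(mirrored, smoothing = 1)
  for (i in seq_along(mm$maps))
    expect_equal(mm2$maps[[i]], mirror(mm$maps[[i]]), tolerance = 1e-12)
})

test_that("signal masks are binary, empty for static baselines, and confined to the signaller", {
  static <- image_sequence(replicate(3, matrix(0.5, 40, 40), simplify = FALSE), 25)
  ms <- signal_mask(static)
  for (m in ms$masks) expect_identical(max(m), 0)

  p <- tiny_scene()
  ms <- signal_mask(p$baseline, smoothing = 0, dilate = 1)
  strict <- signal_mask(p$baseline, smoothing = 0, dilate = 0)
  any_on <- FALSE
  for (i in seq_along(ms$masks)) {
    expect_true(all(ms$masks[[i]] %in% c(0, 1)))
    # dilated mask support stays inside the truth region expanded by the
    # dilation radius + bbox margin
    tm <- motionsalience:::truth_mask(p, i, expand = 2)
    expect_false(any(ms$masks[[i]] > 0 & !tm))
    # dilation only grows the mask
    expect_true(all(ms$masks[[i]] >= strict$masks[[i]]))
    if (any(ms$masks[[i]] > 0)) any_on <- TRUE
  }
  expect_true(any_on)
})

test_that("baseline motion extent reproduces the archetype ordering", {
  exts <- lapply(DISPLAY_ARCHETYPES, function(d) {
    p <- generate_scene(scene_spec(d, "SPARSE_BURNT_CD", 1, 5))
    motion_extent(detect_motion(p$baseline))
  })
  names(exts) <- DISPLAY_ARCHETYPES
  totals <- vapply(exts, sum, numeric(1))
  expect_lt(totals[["CONTINUOUS_LOW_CF"]],
            min(totals[setdiff(DISPLAY_ARCHETYPES, "CONTINUOUS_LOW_CF")]))
  # intermittency: more rest frames in the first 60% of the display window
  intro <- seq_len(round(0.6 * 0.8 * (length(exts[[1]]) + 1)))
  zeroes <- vapply(exts, function(e) sum(e[intro] == 0), numeric(1))
  expect_gt(zeroes[["INTERMITTENT_AM"]], zeroes[["CONTINUOUS_RAPID_GL"]])
  expect_gt(zeroes[["INTERMITTENT_AM"]], zeroes[["RAMPING_CD"]])
})
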