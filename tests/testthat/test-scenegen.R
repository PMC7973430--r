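test_that("display envelopes start from rest and stay in [0, 1]", {
  tt <- seq(0, 8, by = 0.04)
  for (a in DISPLAY_ARCHETYPES) {
    env <- display_envelope(a, tt, 8)
    expect_identical(env[1], 0)
    expect_true(all(env >= 0 & env <= 1))
  }
  expect_error(display_envelope("PUSHUP_XX", 0.5, 8), "PUSHUP_XX")
})

test_that("ramping archetype is monotone non-decreasing over the sequence", {
  tt <- seq(0, 8, by = 0.01)
  env <- display_envelope("RAMPING_CD", tt, 8)
  expect_true(all(diff(env) >= 0))
})

test_that("the low-continuous archetype generates the least movement", {
  tt <- seq(0, 8, by = 0.04)
  ints <- vapply(DISPLAY_ARCHETYPES,
                 function(a) mean(display_envelope(a, tt, 8)), numeric(1))
  cf <- ints[["CONTINUOUS_LOW_CF"]]
  others <- ints[setdiff(DISPLAY_ARCHETYPES, "CONTINUOUS_LOW_CF")]
  expect_lt(cf, min(others))
  expect_lt(cf, mean(others))
})

test_that("intermittent archetype has rest gaps in its intro, continuous ones do not", {
  tt <- seq(0.3, 0.6 * 0.8 * 8, by = 0.04)  # intro, past display onset
  am <- display_envelope("INTERMITTENT_AM", tt, 8)
  expect_gt(mean(am == 0), 0.05)
  for (a in c("CONTINUOUS_RAPID_GL", "CONTINUOUS_LOW_CF", "RAMPING_CD"))
    expect_true(all(display_envelope(a, tt, 8) > 0))
})

test_that("wind gain is zero in calm air, convex, and habitat-ordered", {
  for (h in HABITAT_ARCHETYPES) {
    expect_identical(wind_gain(h, 0), 0)
    g <- wind_gain(h, seq(0.1, 1, by = 0.1))
    expect_true(all(diff(g) > 0))
    expect_lt(wind_gain(h, 0.5), 0.5 * wind_gain(h, 1.0))
  }
  expect_gt(wind_gain("DENSE_CLOSE_AM", 1.0), wind_gain("SPARSE_BURNT_CD", 1.0))
  expect_error(wind_gain("DENSE_CLOSE_AM", 1.2), "\\[0, 1\\]")
  expect_error(wind_gain("DENSE_CLOSE_AM", -0.1), "\\[0, 1\\]")
})

test_that("scene_spec rejects invalid cells", {
  expect_error(scene_spec("INTERMITTENT_AM", "DENSE_CLOSE_AM", 0, 1), "1..10")
  expect_error(scene_spec("INTERMITTENT_AM", "DENSE_CLOSE_AM", 11, 1), "1..10")
  expect_error(scene_spec("INTERMITTENT_AM", "DENSE_CLOSE_AM", 5, 1,
                          width = 16), ">= 32")
  expect_error(scene_spec("INTERMITTENT_AM", "DENSE_CLOSE_AM", 5, 1,
                          fps = 25, duration = 0.03), ">= 2")
})

test_that("scene generation is bit-deterministic and geometrically consistent", {
  p1 <- tiny_scene()
  p2 <- tiny_scene()
  expect_identical(p1$composite$frames, p2$composite$frames)
  expect_identical(p1$baseline$frames, p2$baseline$frames)
  expect_identical(p1$truth_region, p2$truth_region)
  expect_equal(length(p1$composite$frames), length(p1$baseline$frames))
  expect_identical(dim(p1$composite$frames[[1]]), dim(p1$baseline$frames[[1]]))
  expect_equal(p1$composite$fps, p1$baseline$fps)
  rng <- range(unlist(p1$composite$frames))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("baseline is static outside the signaller region", {
  p <- tiny_scene()
  for (i in seq_len(length(p$baseline$frames) - 1)) {
    d <- abs(p$baseline$frames[[i + 1]] - p$baseline$frames[[i]])
    d[motionsalience:::truth_mask(p, i, expand = 0)] <- 0
    expect_identical(max(d), 0)
  }
})

test_that("a zero-amplitude display yields a fully static baseline", {
  p <- tiny_scene(display_scale = 0)
  for (i in seq_len(length(p$baseline$frames) - 1))
    expect_identical(p$baseline$frames[[i + 1]], p$baseline$frames[[i]])
})

test_that("calm wind leaves near-zero motion extent outside the signaller", {
  ext <- validate_noise_gradient("DENSE_CLOSE_AM", seed = 11, smoothing = 0,
                                 duration = 1.2)
  expect_lt(ext[1] / (96 * 72), 0.05)
  expect_lt(ext[1], 0.6 * ext[10])
})

test_that("noise gradient is non-decreasing, non-linear, and zero for a dead habitat", {
  for (h in HABITAT_ARCHETYPES) {
    g <- validate_noise_gradient(h, seed = 11)
    expect_false(is.unsorted(g))
    expect_gt(g[10], g[1])
    expect_gt(length(unique(round(diff(g), 6))), 1)  # increments vary
  }
  expect_identical(validate_noise_gradient("DENSE_CLOSE_AM", 11,
                                           duration = 1.2, gain_scale = 0),
                   rep(0, 10))
})

test_that("the wind-level controller grid is uniform on (0, 1]", {
  cells <- (1:10) / 10
  expect_equal(diff(cells), rep(0.1, 9))
  expect_equal(range(cells), c(0.1, 1))
})

test_that("noise extents agree with an independent gradient-support oracle", {
  sp <- scene_spec("CONTINUOUS_LOW_CF", "SPARSE_BURNT_CD", 6, 11,
                   width = 64, height = 48, duration = 1.2, display_scale = 0)
  p <- generate_scene(sp)
  mm <- detect_motion(p$composite, smoothing = 0)
  for (i in seq_along(mm$maps)) {
    tm <- motionsalience:::truth_mask(p, i, expand = 1)
    got <- mm$maps[[i]]; got[tm] <- 0
    want <- oracle_motion_support(p$composite$frames[[i]],
                                  p$composite$frames[[i + 1]])
    want[tm] <- FALSE
    expect_identical(sum(got > 0), sum(want))
  }
})

test_that("scene pairs roundtrip through PNG and TIFF containers", {
  p <- tiny_scene(duration = 0.2)
  for (fmt in c("png", "tiff")) {
    dir <- file.path(tempfile(), fmt)
    write_scene(p, dir, format = fmt)
    q <- read_scene(dir)
    tol <- if (fmt == "png") 1e-12 else 1e-4
    expect_equal(q$composite$frames, p$composite$frames, tolerance = tol)
    expect_equal(q$baseline$frames, p$baseline$frames, tolerance = tol)
    expect_identical(q$truth_region, p$truth_region)
    expect_identical(q$spec$display, p$spec$display)
    expect_identical(q$spec$wind_level, p$spec$wind_level)
  }
})
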