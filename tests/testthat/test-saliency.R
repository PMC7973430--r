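test_that("Gabor kernels are zero-mean so constant frames give zero response", {
  bank <- gabor_bank()
  for (o in 1:4) {
    expect_lt(abs(sum(bank$cos[[o]])), 1e-12)
    expect_lt(abs(sum(bank$sin[[o]])), 1e-12)
  }
  pyr <- gabor_pyramid(matrix(0.7, 48, 48))
  for (o in 1:4) for (k in 1:9)
    expect_lt(max(pyr$resp[[o]][[k]]), 1e-10)
})

test_that("pyramid geometry: nine dyadic levels down to a 1:256 sampling ratio", {
  dims <- motionsalience:::pyramid_level_dims(512, 512, 9)
  expect_identical(dims[9, ], c(2L, 2L))          # 512 / 2^8
  expect_identical(dims[1, ], c(512L, 512L))
  pyr <- gabor_pyramid(matrix(0.5, 512, 512))
  expect_identical(dim(pyr$resp[[1]][[9]]), c(2L, 2L))
  d96 <- motionsalience:::pyramid_level_dims(72, 96, 9)
  expect_identical(d96[, 1], as.integer(c(72, 36, 18, 9, 5, 3, 2, 1, 1)))
  expect_identical(d96[, 2], as.integer(c(96, 48, 24, 12, 6, 3, 2, 1, 1)))
  expect_error(gabor_pyramid(matrix(0.5, 8, 8)), "filter support")
})

test_that("level-1 responses match a dense plain-R convolution oracle", {
  set.seed(3)
  img <- matrix(runif(20 * 20), 20, 20)
  bank <- gabor_bank()
  pyr <- gabor_pyramid(img, bank)
  for (o in c(1, 2)) {
    want <- sqrt(oracle_conv2(img, bank$cos[[o]])^2 +
                 oracle_conv2(img, bank$sin[[o]])^2)
    expect_equal(pyr$resp[[o]][[1]], want, tolerance = 1e-12)
  }
})

test_that("oriented gratings drive their own orientation channel", {
  pyr <- gabor_pyramid(grating(64))      # horizontal stripes
  expect_gt(mean(pyr$resp[[1]][[1]]), 100 * mean(pyr$resp[[3]][[1]]))
  pyr_v <- gabor_pyramid(grating(64, vertical = TRUE))
  expect_gt(mean(pyr_v$resp[[3]][[1]]), 100 * mean(pyr_v$resp[[1]][[1]]))
})

test_that("Reichardt correlation reproduces the hand-evaluated opponent product", {
  prev <- matrix(c(0, 1, 0, 0), 1, 4)
  curr <- matrix(c(0, 0, 1, 0), 1, 4)
  expect_identical(as.vector(reichardt_pair(prev, curr, 1, 0)),
                   c(0, 1, 0, 0))
  # magnitude is symmetric under frame exchange
  expect_identical(reichardt_pair(curr, prev, 1, 0),
                   reichardt_pair(prev, curr, 1, 0))
  expect_error(reichardt_pair(matrix(0, 2, 2), matrix(0, 3, 3), 1, 0),
               "identical shape")
})

test_that("static input gives an all-zero motion pyramid", {
  p <- gabor_pyramid(grating(32))
  mp <- reichardt_motion(p, p)
  for (o in 1:4) for (k in 1:9)
    expect_identical(max(mp$resp[[o]][[k]]), 0)
})

test_that("signed Reichardt response prefers the true translation direction", {
  p1 <- gabor_pyramid(grating(64, vertical = TRUE))
  p2 <- gabor_pyramid(grating(64, vertical = TRUE, shift = 1))  # rightward
  right <- sum(reichardt_pair(p1$resp[[3]][[1]], p2$resp[[3]][[1]],
                              1, 0, signed = TRUE))
  left <- sum(reichardt_pair(p1$resp[[3]][[1]], p2$resp[[3]][[1]],
                             -1, 0, signed = TRUE))
  expect_gt(right, 0)
  expect_gt(right, left)
})

test_that("activation matches dense stationary solutions and the worked 3-cell case", {
  for (method in c("direct", "power")) {
    got <- gbvs_activation(matrix(c(1, 1, exp(1)), 1, 3), sigma = Inf,
                           method = method)
    expect_equal(as.vector(got), c(0.25, 0.25, 0.5), tolerance = 1e-7)
  }
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    f <- matrix(runif(n * n), n, n)
    got <- gbvs_activation(f, sigma = 3)
    expect_lt(max(abs(got - oracle_activation(f, 3))), 1e-8)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("degenerate activation inputs fall back to the uniform map", {
  expect_equal(gbvs_activation(matrix(1, 2, 2)), matrix(0.25, 2, 2))
  expect_equal(gbvs_activation(matrix(0, 2, 2)), matrix(0.25, 2, 2))
  expect_error(gbvs_activation(matrix(-1, 2, 2)), "non-negative")
  expect_error(gbvs_activation(matrix(1, 1, 1)), ">= 2 cells")
})

test_that("normalisation solves its two-state chain and conserves mass", {
  got <- gbvs_normalize(matrix(c(0.25, 0.75), 1, 2), sigma = Inf)
  expect_equal(as.vector(got), c(0.25, 0.75), tolerance = 1e-9)
  u <- matrix(1 / 9, 3, 3)
  expect_equal(gbvs_normalize(u, sigma = Inf), u, tolerance = 1e-9)
  set.seed(5)
  a <- matrix(runif(16), 4, 4); a <- a / sum(a)
  expect_equal(sum(gbvs_normalize(a)), 1, tolerance = 1e-12)
  expect_error(gbvs_normalize(matrix(c(0.4, 0.4), 1, 2)), "sum to 1")
})

test_that("saliency of a static sequence is identically zero", {
  frames <- replicate(3, grating(32), simplify = FALSE)
  sal <- saliency_map(image_sequence(frames, 25))
  for (m in sal$maps) expect_identical(max(m), 0)
})

test_that("saliency maps live on [0, 1] at frame resolution with max 1 on motion", {
  p <- tiny_scene(duration = 0.4)
  sal <- saliency_map(p$composite)
  expect_length(sal$maps, length(p$composite$frames) - 1)
  for (m in sal$maps) {
    expect_identical(dim(m), dim(p$composite$frames[[1]]))
    expect_gte(min(m), 0); expect_lte(max(m), 1)
    if (max(m) > 0) expect_equal(max(m), 1)
  }
})

test_that("a lone moving dot is the saliency argmax near its true position", {
  frames <- lapply(1:6, function(i) {
    m <- matrix(0.5, 48, 48); m[20:23, (8 + 3 * i):(11 + 3 * i)] <- 1; m
  })
  sal <- saliency_map(image_sequence(frames, 25))
  cell_px <- 48 / motionsalience:::working_dims(48, 48, 8)[1]
  for (i in seq_along(sal$maps)) {
    am <- which(sal$maps[[i]] == max(sal$maps[[i]]), arr.ind = TRUE)[1, ]
    dot <- c(21.5, 9.5 + 3 * i + 1.5)   # centre straddling the frame pair
    expect_lt(max(abs(am - dot)), 2 * cell_px + 1)
  }
})

test_that("the fused saliency driver equals the composition of its stages", {
  p <- tiny_scene(duration = 0.2, width = 48, height = 40)
  seq <- p$composite
  params <- saliency_params()
  sal <- saliency_map(seq, params)
  bank <- gabor_bank(params$wavelength, params$sigma_gabor)
  wd <- motionsalience:::working_dims(nrow(seq$frames[[1]]),
                                      ncol(seq$frames[[1]]), params$cell_px)
  pyr_prev <- gabor_pyramid(seq$frames[[1]], bank, params$n_levels)
  for (i in seq_len(length(seq$frames) - 1)) {
    pyr_curr <- gabor_pyramid(seq$frames[[i + 1]], bank, params$n_levels)
    acc <- matrix(0, wd[1], wd[2])
    any_motion <- FALSE
    raw <- list()
    for (o in 1:4) {
      d <- bank$dirs[o, ] * params$shift
      for (k in seq_len(params$n_levels)) {
        raw[[length(raw) + 1]] <-
          reichardt_pair(pyr_prev$resp[[o]][[k]], pyr_curr$resp[[o]][[k]],
                         d[1], d[2]) +
          reichardt_pair(pyr_prev$resp[[o]][[k]], pyr_curr$resp[[o]][[k]],
                         -d[1], -d[2])
      }
    }
    gmax <- max(vapply(raw, max, numeric(1)))
    for (rp in raw) {
      if (max(rp) <= 0.01 * gmax || max(rp) <= 0) next   # silence gate
      any_motion <- TRUE
      # pair-global normalisation with the driver noise floor
      feat <- pmax(resize_map(rp, wd[1], wd[2]) / gmax, 0.01)
      acc <- acc + gbvs_activation(feat, sigma = params$sigma_graph,
                                   eps = params$eps)
    }
    want <- matrix(0, nrow(seq$frames[[1]]), ncol(seq$frames[[1]]))
    if (any_motion) {
      master <- gbvs_normalize(acc / sum(acc), sigma = params$sigma_graph) *
        sum(acc)
      want <- pmax(resize_map(master, nrow(want), ncol(want)), 0)
    }
    if (max(want) > 0) want <- want / max(want)
    expect_equal(sal$maps[[i]], want, tolerance = 1e-6)
    pyr_prev <- pyr_curr
  }
})

test_that("raising the moving object's contrast does not lower its masked salience", {
  mk_seq <- function(contrast) {
    lapply(1:5, function(i) {
      m <- matrix(0.5, 48, 48)
      m[30:34, (30 + round(1.5 * i)):(34 + round(1.5 * i))] <- 0.5 + 0.2  # distractor
      m[10:13, (8 + 3 * i):(11 + 3 * i)] <- 0.5 + contrast                # target
      m
    })
  }
  mask <- matrix(0, 48, 48); mask[5:20, 5:40] <- 1
  masks <- structure(list(masks = replicate(4, mask, simplify = FALSE),
                          grid_factor = 1L), class = "mask_sequence")
  ms <- vapply(c(0.1, 0.3, 0.5), function(ct) {
    sal <- saliency_map(image_sequence(mk_seq(ct), 25))
    mean(masked_salience(sal, masks))
  }, numeric(1))
  expect_true(all(diff(ms) >= -1e-9))
})
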