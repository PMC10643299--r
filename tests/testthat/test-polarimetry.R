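test_that("demosaic extracts each subpixel by its layout angle", {
  # pixels [[7,5],[3,9]] with layout [[90,45],[135,0]]
  m <- raw_mosaic(matrix(c(7, 3, 5, 9), 2, 2), bit_depth = 8)
  sub <- demosaic(m)
  expect_equal(sub$I0, matrix(9, 1, 1))
  expect_equal(sub$I45, matrix(5, 1, 1))
  expect_equal(sub$I90, matrix(7, 1, 1))
  expect_equal(sub$I135, matrix(3, 1, 1))

  const <- raw_mosaic(matrix(42, 4, 4), bit_depth = 8)
  sub4 <- demosaic(const)
  for (im in sub4) expect_equal(im, matrix(42, 2, 2))
})

test_that("demosaic / interleave is a lossless round trip", {
  set.seed(7)
  px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  m <- raw_mosaic(px, bit_depth = 8)
  expect_identical(interleave(demosaic(m), m$layout), px + 0)
})

test_that("mosaic construction validates dimensions, range and layout", {
  expect_error(raw_mosaic(matrix(0, 3, 4), 8), "even")
  expect_error(raw_mosaic(matrix(300, 2, 2), 8), "\\[0, 255\\]")
  expect_error(raw_mosaic(matrix(0, 2, 2), 8,
                          layout = matrix(c(0, 45, 90, 90), 2, 2)),
               "exactly once")
})

test_that("Stokes parameters follow the pairwise-difference convention", {
  u <- function(v) matrix(v, 1, 1)
  s <- compute_stokes(u(100), u(100), u(100), u(100))   # unpolarized
  expect_equal(c(s$S0, s$S1, s$S2), c(200, 0, 0))
  s <- compute_stokes(u(200), u(100), u(0), u(100))     # horizontal
  expect_equal(c(s$S0, s$S1, s$S2), c(200, 200, 0))
  s <- compute_stokes(u(100), u(200), u(100), u(0))     # 45 degrees
  expect_equal(c(s$S0, s$S1, s$S2), c(200, 0, 200))
  expect_error(compute_stokes(matrix(0, 2, 2), u(0), u(0), u(0)),
               "identical dimensions")
})

test_that("dop_aop recovers canonical polarization states", {
  u <- function(v) matrix(v, 1, 1)
  horiz <- dop_aop(compute_stokes(u(200), u(100), u(0), u(100)))
  expect_equal(horiz$dop[1, 1], 1)
  expect_equal(horiz$aop[1, 1], 0)
  unpol <- dop_aop(compute_stokes(u(100), u(100), u(100), u(100)))
  expect_equal(unpol$dop[1, 1], 0)
  expect_equal(unpol$aop[1, 1], 0)   # undefined angle reported as 0
})

test_that("noiseless quantized round trip recovers dop=0.5 to sub-lsb accuracy", {
  set.seed(21)
  # bright unsaturated field: worst-case rounding error stays below 1/2^12
  scene <- stokes_scene(s0 = matrix(runif(256, 5200, 5455), 16),
                        dop = 0.5, aop = 0, grid_size = c(16, 16))
  maps <- mosaic_to_maps(render_mosaic(scene, bit_depth = 12L))
  expect_true(all(maps$mask == "valid"))
  expect_lt(max(abs(maps$dop - 0.5)), 1 / 2^12)
})

test_that("dop above 1 from noise is clipped and counted", {
  s <- compute_stokes(matrix(150, 1, 1), matrix(50, 1, 1),
                      matrix(10, 1, 1), matrix(50, 1, 1))
  maps <- dop_aop(s)   # sqrt(S1^2)/S0 = 140/130 > 1
  expect_equal(maps$dop[1, 1], 1)
  expect_equal(attr(maps, "n_clipped"), 1L)
})

test_that("exposure mask flags saturated superpixels and dark pixels", {
  px <- matrix(100, 4, 4)
  px[1, 1] <- 255                       # one saturated subpixel, superpixel (1,1)
  px[3:4, 3:4] <- 0                     # dark superpixel (2,2)
  m <- raw_mosaic(px, bit_depth = 8)
  maps <- mosaic_to_maps(m, saturation_margin = 0, floor_threshold = 1)
  expect_equal(maps$mask[1, 1], "overexposed")
  expect_equal(maps$mask[2, 2], "underexposed")
  expect_equal(maps$mask[1, 2], "valid")
})

test_that("overexposed set grows monotonically with the saturation margin", {
  set.seed(13)
  px <- matrix(sample(200:255, 144, replace = TRUE), 12, 12)
  m <- raw_mosaic(px, bit_depth = 8)
  prev <- matrix(FALSE, 6, 6)
  for (margin in c(0, 10, 30, 55)) {
    over <- mosaic_to_maps(m, saturation_margin = margin)$mask == "overexposed"
    expect_true(all(over[prev]))   # raising the margin never unmarks a pixel
    prev <- over
  }
})

test_that("dop is invariant to uniform intensity scaling", {
  scene <- random_scene(31)
  sub <- scene_subpixels(scene)
  maps1 <- dop_aop(compute_stokes(sub$I0, sub$I45, sub$I90, sub$I135))
  maps2 <- dop_aop(compute_stokes(0.35 * sub$I0, 0.35 * sub$I45,
                                  0.35 * sub$I90, 0.35 * sub$I135),
                   floor_threshold = 0)
  expect_equal(maps2$dop, maps1$dop, tolerance = 1e-12)
})

test_that("rotating the polarization plane shifts aop by the same angle", {
  base <- random_scene(32)
  for (delta in c(17, 45, 120)) {
    rot <- stokes_scene(base$s0, base$dop, base$aop + delta)
    sub <- scene_subpixels(rot)
    maps <- dop_aop(compute_stokes(sub$I0, sub$I45, sub$I90, sub$I135))
    expect_lt(max(aop_dist(maps$aop, base$aop + delta)), 1e-9)
    base_sub <- scene_subpixels(base)
    base_maps <- dop_aop(compute_stokes(base_sub$I0, base_sub$I45,
                                        base_sub$I90, base_sub$I135))
    expect_equal(maps$dop, base_maps$dop, tolerance = 1e-12)
  }
})

test_that("false-colour rendering honours colormap endpoints and the mask", {
  scene <- stokes_scene(s0 = 1000, dop = 0, aop = 0, grid_size = c(4, 4))
  maps <- mosaic_to_maps(render_mosaic(scene, bit_depth = 12L))
  img <- render_false_colour(maps, "dop")
  # uniform dop = 0 field: every pixel at the colormap's 0 endpoint
  expect_equal(length(unique(as.vector(img[, , 1]))), 1L)
  expect_equal(length(unique(as.vector(img[, , 2]))), 1L)

  maps$mask[1, 1] <- "overexposed"
  maps$mask[2, 2] <- "underexposed"
  img <- render_false_colour(maps, "dop")
  expect_equal(img[1, 1, ], c(255L, 255L, 255L))
  expect_equal(img[2, 2, ], c(0L, 0L, 0L))

  expect_error(render_false_colour(maps, "chroma"))
})

test_that("aop colormap is cyclic across the -90/+90 seam", {
  maps <- structure(list(dop = matrix(0.5, 1, 2),
                         aop = matrix(c(-90, 90 - 1e-6), 1, 2),
                         intensity = matrix(100, 1, 2),
                         mask = matrix("valid", 1, 2)),
                    class = "polarization_maps", n_clipped = 0L)
  img <- render_false_colour(maps, "aop")
  expect_lt(max(abs(img[1, 1, ] - img[1, 2, ])), 16)
})

test_that("mosaic image I/O round-trips through TIFF", {
  set.seed(5)
  px <- matrix(sample(0:4095, 64, replace = TRUE), 8, 8)
  m <- raw_mosaic(px, bit_depth = 12L)
  path <- tempfile(fileext = ".tiff")
  write_image(m, path)
  # 16-bit storage of 12-bit counts: recover to the nearest count
  back <- tiff::readTIFF(path) * 4095
  expect_lt(max(abs(back - px)), 0.5)
})
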