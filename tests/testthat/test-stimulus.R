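test_that("angular size follows disc geometry", {
  expect_equal(round(angular_size(12, 35)), 19)         # the standard loom
  expect_equal(angular_size(12, 35), 19.45, tolerance = 0.01)
  expect_equal(angular_size(0, 50), 0)
  d <- 37
  expect_equal(angular_size(2 * d * tan(30 * pi / 180), d), 60)
  expect_error(angular_size(12, 0), "positive")
  expect_error(angular_size(-1, 10), "non-negative")
})

test_that("expansion profile expands monotonically then holds at full size", {
  for (profile in c("constant_approach", "exponential")) {
    spec <- loom_spec(profile = profile)
    prof <- expansion_profile(spec)
    theta_max <- angular_size(12, 35)
    expanding <- prof$time_s <= spec$expand_duration
    expect_true(all(diff(prof$theta_deg[expanding]) > 0))
    expect_equal(prof$theta_deg[prof$time_s > spec$expand_duration],
                 rep(theta_max, sum(!expanding)), tolerance = 1e-9)
    expect_equal(prof$theta_deg[1], spec$theta_start, tolerance = 1e-9)
    # mid-hold plateau equals the end-of-expansion angle
    i_mid <- which.min(abs(prof$time_s - (spec$expand_duration +
                                            spec$hold_duration / 2)))
    i_end <- which.min(abs(prof$time_s - spec$expand_duration))
    expect_equal(prof$theta_deg[i_mid], prof$theta_deg[i_end],
                 tolerance = 1e-9)
  }
})

test_that("constant-approach profile matches a frame-stepped disc simulation", {
  spec <- loom_spec(theta_start = 1, expand_duration = 3)
  prof <- expansion_profile(spec)
  # independent simulation: a 6 cm radius disc closing at constant speed,
  # distance stepped frame by frame from the boundary conditions
  R <- 6; D <- 35; T <- 3
  d0 <- R / tan(0.5 * pi / 180)          # distance where angle is 1 degree
  v <- (d0 - D) / T
  n_exp <- sum(prof$time_s <= T)
  d <- d0 - v * (seq_len(n_exp) - 1) / spec$frame_rate
  theta_sim <- 2 * atan(R / d) * 180 / pi
  expect_equal(prof$theta_deg[seq_len(n_exp)], theta_sim, tolerance = 1e-9)
})

test_that("unreachable loom boundary conditions are rejected", {
  expect_error(loom_spec(theta_start = 25), "\\[0, full-size angle\\)")
})

test_that("Weber and DoP contrast follow their definitions", {
  expect_equal(weber_contrast(158, 158), 0)
  expect_equal(weber_contrast(79, 158), -0.5)
  expect_equal(weber_contrast(10, 5), 1)
  expect_error(weber_contrast(10, 0), "positive")

  expect_equal(dop_contrast(0.5, 0.5), 0)
  expect_equal(dop_contrast(0.67, 0.5), 0.17)
  expect_equal(dop_contrast(0, 0.5), -0.5)
  expect_error(dop_contrast(1.2, 0.5), "\\[0, 1\\]")
})

test_that("grey_for_target inverts the identity calibration exactly", {
  calib <- identity_calibration()
  expect_equal(grey_for_target(calib, "intensity", 158, -0.5), 79)
  expect_equal(grey_for_target(calib, "intensity", 158, 0), 158)
  expect_equal(grey_for_target(calib, "polarization", 127.5, 0), 127.5)
})

test_that("grey_for_target inverts random monotone calibrations", {
  set.seed(17)
  for (rep in 1:20) {
    grey <- sort(sample(0:255, 24))
    calib <- screen_calibration(grey,
                                radiance = cumsum(runif(24, 0.1, 2)),
                                dop = sort(runif(24)))
    for (modality in c("intensity", "polarization")) {
      bg <- sample(grey[5:20], 1)
      bg_val <- calib_forward(calib, modality, bg)
      col <- if (modality == "intensity") calib$radiance else calib$dop
      target_val <- runif(1, min(col), max(col))
      target <- if (modality == "intensity") target_val / bg_val - 1
                else target_val - bg_val
      g <- grey_for_target(calib, modality, bg, target)
      achieved <- if (modality == "intensity")
        calib_forward(calib, modality, g) / bg_val - 1
      else calib_forward(calib, modality, g) - bg_val
      expect_equal(achieved, target, tolerance = 1e-6)
    }
  }
})

test_that("out-of-gamut contrast targets name the achievable range", {
  calib <- identity_calibration()
  expect_error(grey_for_target(calib, "intensity", 158, 5),
               "achievable range")
})

test_that("stimulus series are reproducible seeded permutations", {
  cs <- c(-0.5, -0.25, 0, 0.25, 0.5)
  s1 <- generate_series(cs, "polarization", seed = 7)
  s2 <- generate_series(cs, "polarization", seed = 7)
  expect_identical(s1, s2)
  expect_setequal(s1$contrast, cs)
  expect_equal(nrow(s1), length(cs))
  expect_true(all(s1$iti_s >= 60 & s1$iti_s <= 180))
  expect_error(generate_series(numeric(0)), "empty")
})

test_that("the series shuffle is uniform over orderings", {
  set.seed(99)
  cs <- c(1, 2, 3)
  tallies <- table(replicate(10000, {
    paste(generate_series(cs, "intensity", seed = NULL)$contrast,
          collapse = "")
  }))
  expect_equal(length(tallies), 6L)
  freq <- as.vector(tallies) / 10000
  expect_true(all(abs(freq - 1 / 6) < 0.02))
})
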