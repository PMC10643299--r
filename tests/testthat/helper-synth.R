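# shared fixtures, all generated in code

random_scene <- function(seed, grid = c(8, 8), s0_range = c(3600, 4080),
                         dop_range = c(0.05, 1)) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    npx <- prod(grid)
    stokes_scene(
      s0 = matrix(runif(npx, s0_range[1], s0_range[2]), grid[1]),
      dop = matrix(runif(npx, dop_range[1], dop_range[2]), grid[1]),
      aop = matrix(runif(npx, -90, 90), grid[1]))
  })
}

# full inverse pipeline: mosaic -> polarization maps
mosaic_to_maps <- function(mosaic, ...) {
  sub <- demosaic(mosaic)
  dop_aop(compute_stokes(sub$I0, sub$I45, sub$I90, sub$I135), mosaic, ...)
}

# circular distance between angles of polarization (180-degree period)
aop_dist <- function(a, b) {
  d <- abs(((a - b + 90) %% 180) - 90)
  pmin(d, 180 - d)
}

make_trial <- function(kinds = character(), onsets = numeric(),
                       pre_retreat = FALSE, order = 1) {
  trial_record("c1", "C_rugosus", "polarization", 0.25, order,
               behaviours = data.frame(kind = kinds, onset_s = onsets),
               pre_stimulus_full_retreat = pre_retreat)
}
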