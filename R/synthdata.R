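# Ground-truth-known synthetic inputs for every pipeline stage:
# Stokes scenes rendered to DoFP mosaics through the Malus-law forward
# model, and behavioural trial tables drawn from a psychometric observer
# population with per-animal random effects, polarity asymmetry and
# habituation.

#' Construct a Stokes scene
#'
#' Ground truth for the polarimetry forward model: per-pixel total intensity
#' `S0` (counts), degree of polarization and angle of polarization.
#'
#' @param s0 Matrix of intensities (counts, >= 0), or a scalar with
#'   `grid_size`.
#' @param dop Matrix or scalar DoP in `[0, 1]`.
#' @param aop Matrix or scalar AoP in degrees (0 = horizontal).
#' @param grid_size `c(rows, cols)` used to expand scalar fields.
#' @return Object of class `stokes_scene`.
#' @export
stokes_scene <- function(s0, dop, aop = 0, grid_size = NULL) {
  expand <- function(v) {
    if (is.matrix(v)) v else matrix(v, grid_size[1], grid_size[2])
  }
  if (is.null(grid_size)) {
    if (!is.matrix(s0)) stop("grid_size needed for scalar fields", call. = FALSE)
    grid_size <- dim(s0)
  }
  s0 <- expand(s0); dop <- expand(dop); aop <- expand(aop)
  if (any(dop < 0 | dop > 1)) stop("dop must lie in [0, 1]", call. = FALSE)
  if (any(s0 < 0)) stop("S0 must be non-negative", call. = FALSE)
  structure(list(s0 = s0, dop = dop, aop = aop), class = "stokes_scene")
}

#' Uniform scene with a centred disc of differing polarization
#'
#' The canonical stimulus scene: a uniformly polarized background (the
#' playback screens use 50% polarization in the horizontal plane) with a
#' centred disc whose DoP differs. Intensity and AoP (0 degrees,
#' horizontal) are uniform, so the disc exists in polarization contrast
#' only.
#'
#' @param background_dop,disc_dop DoP values in `[0, 1]`.
#' @param disc_radius_px Disc radius in scene pixels.
#' @param grid_size `c(rows, cols)`.
#' @param s0 Uniform intensity in counts.
#' @return A [stokes_scene()].
#' @export
make_disc_scene <- function(background_dop = 0.5, disc_dop = 1,
                            disc_radius_px = 16, grid_size = c(64, 64),
                            s0 = 2000) {
  if (2 * disc_radius_px > min(grid_size))
    stop("disc does not fit inside the grid", call. = FALSE)
  dop <- matrix(background_dop, grid_size[1], grid_size[2])
  cy <- (grid_size[1] + 1) / 2; cx <- (grid_size[2] + 1) / 2
  rr <- matrix(seq_len(grid_size[1]), grid_size[1], grid_size[2])
  cc <- matrix(seq_len(grid_size[2]), grid_size[1], grid_size[2], byrow = TRUE)
  inside <- (rr - cy)^2 + (cc - cx)^2 <= disc_radius_px^2
  dop[inside] <- disc_dop
  stokes_scene(s0 = s0, dop = dop, aop = 0, grid_size = grid_size)
}

#' Ideal-polarizer subpixel intensities of a Stokes scene
#'
#' The continuous Malus-law forward model:
#' `S1 = S0 dop cos(2 aop)`, `S2 = S0 dop sin(2 aop)`, and
#' `I_phi = 0.5 (S0 + S1 cos 2phi + S2 sin 2phi)` for an ideal linear
#' polarizer at angle `phi`. No noise or quantization.
#'
#' @param scene A [stokes_scene()].
#' @return List of matrices `I0`, `I45`, `I90`, `I135`.
#' @export
scene_subpixels <- function(scene) {
  stopifnot(inherits(scene, "stokes_scene"))
  a <- scene$aop * pi / 180
  S1 <- scene$s0 * scene$dop * cos(2 * a)
  S2 <- scene$s0 * scene$dop * sin(2 * a)
  phis <- c(I0 = 0, I45 = 45, I90 = 90, I135 = 135)
  lapply(phis, function(phi) {
    p <- phi * pi / 180
    0.5 * (scene$s0 + S1 * cos(2 * p) + S2 * sin(2 * p))
  })
}

#' Render a Stokes scene to a raw DoFP mosaic
#'
#' Applies the Malus-law forward model per superpixel, adds optional
#' Gaussian read noise, then quantizes to integer counts clipped to the
#' sensor range. Deterministic given `seed`.
#'
#' @param scene A [stokes_scene()] (one scene pixel = one superpixel).
#' @param layout 2x2 polarizer layout.
#' @param bit_depth Sensor bit depth.
#' @param noise_sd Read-noise SD in counts (0 = noiseless).
#' @param seed Optional integer seed.
#' @return A [raw_mosaic()] of twice the scene's dimensions.
#' @export
render_mosaic <- function(scene, layout = default_layout(), bit_depth = 12L,
                          noise_sd = 0, seed = NULL) {
  subs <- scene_subpixels(scene)
  local_seed(seed, {
    if (noise_sd > 0)
      subs <- lapply(subs, function(m)
        m + stats::rnorm(length(m), 0, noise_sd))
    maxval <- 2^bit_depth - 1
    subs <- lapply(subs, function(m) pmin(pmax(round(m), 0), maxval))
    raw_mosaic(interleave(subs, layout), bit_depth = bit_depth, layout = layout)
  })
}

#' Psychometric observer population model
#'
#' Generates behavioural ground truth: response probability follows a
#' 4-parameter sigmoid of absolute contrast with separate half-maxima for
#' positive and negative contrast polarity, each animal carries a Gaussian
#' random intercept on the logit scale, and habituation subtracts a fixed
#' probability per successive trial (matching the line-fit definition of
#' the habituation rate `h`).
#'
#' @param bottom,top Asymptotic response probabilities.
#' @param x50_pos,x50_neg Half-maximum absolute contrast for positive and
#'   negative contrasts.
#' @param slope Sigmoid steepness (1/contrast, on absolute contrast).
#' @param crab_sd SD of the per-animal random intercept (logit units).
#' @param habituation_decrement Response-probability drop per trial (>= 0
#'   for habituation).
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(bottom = 0.1, top = 0.9, x50_pos = 0.2,
                           x50_neg = 0.2, slope = 6, crab_sd = 0.5,
                           habituation_decrement = 0) {
  if (!(bottom >= 0 && bottom <= top && top <= 1))
    stop("need 0 <= bottom <= top <= 1", call. = FALSE)
  if (crab_sd < 0) stop("crab_sd must be >= 0", call. = FALSE)
  structure(list(bottom = bottom, top = top, x50_pos = x50_pos,
                 x50_neg = x50_neg, slope = slope, crab_sd = crab_sd,
                 habituation_decrement = habituation_decrement),
            class = "observer_model")
}

observer_prob <- function(model, contrast) {
  x50 <- ifelse(contrast < 0, model$x50_neg, model$x50_pos)
  sigmoid_response(abs(contrast), model$bottom, model$top, x50, model$slope)
}

#' Simulate behavioural trial tables from an observer population
#'
#' For each animal an intercept offset is drawn from `N(0, crab_sd)`; each
#' trial's response probability is the observer sigmoid of its contrast,
#' shifted by the animal's offset on the logit scale, minus
#' `habituation_decrement * (order - 1)`, clamped to `[0, 1]`; the response
#' is a Bernoulli draw. Presentation order is a fresh randomized series per
#' animal. Deterministic given `seed`.
#'
#' @param model An [observer_model()].
#' @param n_crabs Number of animals.
#' @param contrast_set Contrast levels, one presentation each per series.
#' @param n_series_per_crab Series per animal (the playback design uses 1).
#' @param modality Stimulus modality label.
#' @param species Species label.
#' @param seed Optional integer seed.
#' @return Per-trial data frame with columns `crab_id`, `species`,
#'   `modality`, `contrast`, `order`, `response`, `p_true`,
#'   `pre_stim_retreat`.
#' @export
simulate_trials <- function(model, n_crabs, contrast_set,
                            n_series_per_crab = 1,
                            modality = "polarization",
                            species = "synthetic", seed = NULL) {
  stopifnot(inherits(model, "observer_model"), n_crabs >= 1,
            length(contrast_set) >= 1)
  local_seed(seed, {
    rows <- vector("list", n_crabs * n_series_per_crab)
    k <- 0L
    for (i in seq_len(n_crabs)) {
      offset <- stats::rnorm(1, 0, model$crab_sd)
      for (s in seq_len(n_series_per_crab)) {
        series <- generate_series(contrast_set, modality, seed = NULL)
        p0 <- observer_prob(model, series$contrast)
        p0 <- pmin(pmax(p0, 1e-9), 1 - 1e-9)
        p <- stats::plogis(stats::qlogis(p0) + offset) -
          model$habituation_decrement * (series$order - 1)
        p <- pmin(pmax(p, 0), 1)
        k <- k + 1L
        rows[[k]] <- data.frame(
          crab_id = sprintf("crab%03d", i), species = species,
          modality = modality, contrast = series$contrast,
          order = series$order,
          response = stats::rbinom(nrow(series), 1, p),
          p_true = p, pre_stim_retreat = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate trials from a linear-logit response model
#'
#' The generating model matched to the mixed-effects logistic analysis:
#' `logit p = beta0 + beta_contrast * contrast + b_i` with
#' `b_i ~ N(0, crab_sd)` per animal and no habituation. Used for GLMM
#' calibration and power studies, where the effect of interest is linear on
#' the logit scale (unlike the saturating psychometric observer).
#'
#' @param beta0 Intercept (logit scale).
#' @param beta_contrast Contrast slope (logit scale, 1/contrast).
#' @param crab_sd SD of the per-animal random intercept.
#' @param n_crabs Number of animals.
#' @param contrast_set Contrast levels, one presentation each per animal in
#'   randomized order.
#' @param modality,species Labels.
#' @param seed Optional integer seed.
#' @return Per-trial data frame as from [simulate_trials()].
#' @export
simulate_logit_trials <- function(beta0, beta_contrast, crab_sd, n_crabs,
                                  contrast_set, modality = "polarization",
                                  species = "synthetic", seed = NULL) {
  local_seed(seed, {
    rows <- vector("list", n_crabs)
    for (i in seq_len(n_crabs)) {
      offset <- stats::rnorm(1, 0, crab_sd)
      series <- generate_series(contrast_set, modality, seed = NULL)
      p <- stats::plogis(beta0 + beta_contrast * series$contrast + offset)
      rows[[i]] <- data.frame(
        crab_id = sprintf("crab%03d", i), species = species,
        modality = modality, contrast = series$contrast,
        order = series$order, response = stats::rbinom(nrow(series), 1, p),
        p_true = p, pre_stim_retreat = FALSE)
    }
    do.call(rbind, rows)
  })
}
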