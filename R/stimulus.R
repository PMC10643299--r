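# Expanding-disc looming stimuli in intensity (Weber) or polarization (DoP)
# contrast, with screen-calibration inversion and randomized trial series.

#' Visual angle subtended by a disc
#'
#' @param diameter Disc diameter (cm), >= 0.
#' @param distance Viewing distance (cm), > 0.
#' @return Angular size `2 atan(diameter / (2 distance))` in degrees.
#' @examples
#' angular_size(12, 35)   # ~19 degrees, the standard loom end point
#' @export
angular_size <- function(diameter, distance) {
  if (any(distance <= 0)) stop("viewing distance must be positive", call. = FALSE)
  if (any(diameter < 0)) stop("diameter must be non-negative", call. = FALSE)
  2 * atan(diameter / (2 * distance)) * 180 / pi
}

#' Specify an expanding-disc loom
#'
#' Defaults follow the playback assay used with terrestrial hermit crabs:
#' a 12 cm disc viewed from 35 cm (about 19 degrees fully expanded),
#' expanding over 3 s and held 2 s at full size. Marine trials use a 10 s
#' expansion (`expand_duration = 10`). The constant-approach profile cannot
#' start from exactly 0 degrees in finite time, so expansion starts from a
#' small configurable angle (default 0.5 degrees).
#'
#' @param disc_diameter Disc diameter (cm).
#' @param viewing_distance Viewing distance (cm).
#' @param expand_duration Expansion time (s).
#' @param hold_duration Hold time at full size (s).
#' @param theta_start Initial visual angle (degrees); must be smaller than
#'   the full-size angle and, for the exponential profile, positive.
#' @param frame_rate Display frame rate (Hz).
#' @param profile `"constant_approach"` (an object closing at constant
#'   speed) or `"exponential"` (exponential angular growth).
#' @return Object of class `loom_spec`.
#' @export
loom_spec <- function(disc_diameter = 12, viewing_distance = 35,
                      expand_duration = 3, hold_duration = 2,
                      theta_start = 0.5, frame_rate = 60,
                      profile = c("constant_approach", "exponential")) {
  profile <- match.arg(profile)
  if (disc_diameter <= 0 || viewing_distance <= 0)
    stop("disc_diameter and viewing_distance must be positive", call. = FALSE)
  if (expand_duration <= 0) stop("expand_duration must be positive", call. = FALSE)
  theta_max <- angular_size(disc_diameter, viewing_distance)
  if (theta_start < 0 || theta_start >= theta_max)
    stop("theta_start must lie in [0, full-size angle)", call. = FALSE)
  structure(list(disc_diameter = disc_diameter,
                 viewing_distance = viewing_distance,
                 expand_duration = expand_duration,
                 hold_duration = hold_duration,
                 theta_start = theta_start, frame_rate = frame_rate,
                 profile = profile),
            class = "loom_spec")
}

#' Frame-by-frame angular expansion profile of a loom
#'
#' For the constant-approach profile the disc edge follows
#' `theta(t) = 2 atan(R / (v (t_end + eps - t)))`, i.e. an object of radius
#' `R` approaching at constant speed `v`; `v` and `eps` are solved from the
#' boundary conditions `theta(0) = theta_start` and
#' `theta(expand_duration) =` full angular size. The exponential profile
#' grows the angle geometrically, `theta(t) = theta_max * k^(t - T)`.
#' After expansion the angle is held constant for `hold_duration`.
#'
#' @param spec A [loom_spec()].
#' @return Data frame with columns `frame`, `time_s`, `theta_deg`.
#' @export
expansion_profile <- function(spec) {
  stopifnot(inherits(spec, "loom_spec"))
  R <- spec$disc_diameter / 2
  D <- spec$viewing_distance
  T <- spec$expand_duration
  theta_max <- angular_size(spec$disc_diameter, spec$viewing_distance)
  t <- seq(0, T + spec$hold_duration, by = 1 / spec$frame_rate)
  expanding <- t <= T
  theta <- rep(theta_max, length(t))
  if (spec$profile == "constant_approach") {
    # distance at t=0 is R / tan(theta_start/2); at t=T it is D
    d0 <- R / tan(spec$theta_start / 2 * pi / 180)
    v <- (d0 - D) / T
    if (!is.finite(v) || v <= 0)
      stop("unreachable loom boundary conditions (theta_start too large?)",
           call. = FALSE)
    eps <- D / v
    theta[expanding] <- 2 * atan(R / (v * (T + eps - t[expanding]))) * 180 / pi
  } else {
    if (spec$theta_start <= 0)
      stop("exponential profile requires theta_start > 0", call. = FALSE)
    k <- (theta_max / spec$theta_start)^(1 / T)
    theta[expanding] <- theta_max * k^(t[expanding] - T)
  }
  data.frame(frame = seq_along(t), time_s = t, theta_deg = theta)
}

#' Weber contrast of an object against its background
#'
#' `(I_object - I_background) / I_background`; negative values are darker
#' than the background.
#'
#' @param i_object,i_background Radiances (same relative units);
#'   `i_background` must be positive.
#' @return Dimensionless signed contrast.
#' @export
weber_contrast <- function(i_object, i_background) {
  if (any(i_background <= 0))
    stop("background radiance must be positive", call. = FALSE)
  (i_object - i_background) / i_background
}

#' Degree-of-polarization contrast
#'
#' The polarization analogue of intensity contrast: stimulus DoP minus
#' background DoP, so a less-polarized stimulus on a polarized background
#' has negative contrast.
#'
#' @param dop_stimulus,dop_background DoP values in `[0, 1]`.
#' @return Signed contrast in `[-1, 1]`.
#' @export
dop_contrast <- function(dop_stimulus, dop_background) {
  if (any(dop_stimulus < 0 | dop_stimulus > 1 |
          dop_background < 0 | dop_background > 1))
    stop("DoP values must lie in [0, 1]", call. = FALSE)
  dop_stimulus - dop_background
}

#' Screen calibration table
#'
#' Maps display grey levels (0-255, R = G = B) to measured radiance and,
#' for a polarization display, to the degree of polarization produced
#' against the reference background. Radiance is regularised to be strictly
#' increasing (isotonic fit plus minimal tie-breaking) so the mapping is
#' invertible.
#'
#' @param grey Integer grey levels in 0..255, strictly increasing.
#' @param radiance Measured radiance (relative units).
#' @param dop Degree of polarization in `[0, 1]` produced at each grey
#'   level (optional for intensity-only screens).
#' @return Object of class `screen_calibration` (a data frame).
#' @export
screen_calibration <- function(grey, radiance, dop = NULL) {
  if (is.unsorted(grey, strictly = TRUE))
    stop("grey levels must be strictly increasing", call. = FALSE)
  if (any(grey < 0 | grey > 255)) stop("grey levels must be in 0..255", call. = FALSE)
  iso <- stats::isoreg(grey, radiance)$yf
  ties <- c(FALSE, diff(iso) <= 0)
  if (any(ties)) iso <- iso + cumsum(ties) * 1e-9 * max(abs(iso), 1)
  if (!is.null(dop) && any(dop < 0 | dop > 1))
    stop("dop must lie in [0, 1]", call. = FALSE)
  out <- data.frame(grey = grey, radiance = iso)
  if (!is.null(dop)) out$dop <- dop
  class(out) <- c("screen_calibration", "data.frame")
  out
}

#' Identity screen calibration
#'
#' A synthetic calibration for testing and simulation: radiance equals the
#' grey level and DoP ramps linearly from 0 at grey 0 to 1 at grey 255.
#'
#' @return A [screen_calibration()].
#' @export
identity_calibration <- function() {
  screen_calibration(0:255, as.numeric(0:255), (0:255) / 255)
}

#' Forward calibration map: grey level to radiance or DoP
#'
#' Piecewise-linear interpolation of the calibration table.
#'
#' @param calib A [screen_calibration()].
#' @param modality `"intensity"` (returns radiance) or `"polarization"`
#'   (returns DoP).
#' @param grey Grey level(s), possibly fractional, within the table range.
#' @return Interpolated radiance or DoP.
#' @export
calib_forward <- function(calib, modality = c("intensity", "polarization"),
                          grey) {
  modality <- match.arg(modality)
  col <- if (modality == "intensity") "radiance" else "dop"
  if (is.null(calib[[col]]))
    stop("calibration table has no ", col, " column", call. = FALSE)
  stats::approx(calib$grey, calib[[col]], xout = grey, rule = 1)$y
}

#' Grey level achieving a target contrast
#'
#' Inverts the calibration table (piecewise linearly) to find the
#' foreground grey level whose radiance gives the requested Weber contrast
#' (intensity modality) or whose DoP gives the requested DoP contrast
#' (polarization modality) against the background setting.
#'
#' @param calib A [screen_calibration()].
#' @param modality `"intensity"` or `"polarization"`.
#' @param background_grey Background grey level (the background's own
#'   setting in both modalities).
#' @param target_contrast Desired signed contrast.
#' @return Foreground grey level (possibly fractional).
#' @export
grey_for_target <- function(calib, modality = c("intensity", "polarization"),
                            background_grey, target_contrast) {
  modality <- match.arg(modality)
  bg_val <- calib_forward(calib, modality, background_grey)
  col <- if (modality == "intensity") "radiance" else "dop"
  target <- if (modality == "intensity") bg_val * (1 + target_contrast)
            else bg_val + target_contrast
  vals <- calib[[col]]
  if (target < min(vals) || target > max(vals)) {
    ach <- if (modality == "intensity")
      range(vals / bg_val - 1) else range(vals - bg_val)
    stop(sprintf(
      "target contrast %.4g outside the achievable range [%.4g, %.4g]",
      target_contrast, ach[1], ach[2]), call. = FALSE)
  }
  stats::approx(vals, calib$grey, xout = target, ties = "ordered")$y
}

# evaluate expr with a temporary RNG state seeded by `seed`;
# seed = NULL draws from the current stream without disturbing callers' code
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Randomized stimulus presentation series
#'
#' A seeded uniform shuffle of the contrast set, one presentation per
#' contrast, with inter-trial intervals drawn uniformly from the configured
#' range (1-3 minutes by default). Each series uses a single modality;
#' an animal sees one series only, so each series is an independent unit.
#'
#' @param contrast_set Numeric vector of contrasts (each appears once).
#' @param modality `"intensity"` or `"polarization"`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param iti_range Inter-trial interval range in seconds.
#' @return Data frame of class `stimulus_series` with columns `order`,
#'   `modality`, `contrast`, `iti_s`.
#' @export
generate_series <- function(contrast_set,
                            modality = c("intensity", "polarization"),
                            seed = NULL, iti_range = c(60, 180)) {
  modality <- match.arg(modality)
  if (length(contrast_set) == 0) stop("contrast set is empty", call. = FALSE)
  local_seed(seed, {
    ord <- sample.int(length(contrast_set))
    iti <- stats::runif(length(contrast_set), iti_range[1], iti_range[2])
    out <- data.frame(order = seq_along(ord), modality = modality,
                      contrast = contrast_set[ord], iti_s = iti)
    class(out) <- c("stimulus_series", "data.frame")
    out
  })
}
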