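# Stokes polarimetry for division-of-focal-plane (DoFP) polarization cameras.
#
# A DoFP sensor tiles the focal plane with 2x2 "superpixels" whose four
# subpixels carry wire-grid micro-polarizers at 0, 45, 90 and 135 degrees,
# so a single monochrome frame contains enough information to recover the
# linear Stokes parameters (S0, S1, S2) at half the sensor resolution.

#' Default DoFP superpixel layout
#'
#' 2x2 matrix giving the polarizer orientation (degrees) of each subpixel
#' within a superpixel: row/column 1 are the even sensor rows/columns.
#' The default matches the Sony IMX250MZR sensor family used by common
#' machine-vision polarization cameras.
#'
#' @return A 2x2 numeric matrix containing 0, 45, 90 and 135 once each.
#' @export
default_layout <- function() {
  matrix(c(90, 45, 135, 0), nrow = 2, byrow = TRUE)
}

check_layout <- function(layout) {
  if (!is.matrix(layout) || !all(dim(layout) == c(2L, 2L)))
    stop("layout must be a 2x2 matrix", call. = FALSE)
  if (!setequal(as.vector(layout), c(0, 45, 90, 135)))
    stop("layout must contain each of the angles 0, 45, 90, 135 exactly once",
         call. = FALSE)
  invisible(layout)
}

#' Construct a raw polarization-camera mosaic
#'
#' Bundles a single-channel mosaicked image with the metadata needed to
#' interpret it: the sensor bit depth and the 2x2 polarizer layout.
#'
#' @param pixels Numeric matrix of digital numbers (camera counts). Both
#'   dimensions must be even.
#' @param bit_depth Bits per pixel (8 or 12 for the supported cameras).
#' @param layout 2x2 matrix mapping subpixel position to polarizer angle in
#'   degrees; see [default_layout()].
#' @return An object of class `raw_mosaic`.
#' @export
raw_mosaic <- function(pixels, bit_depth = 12L, layout = default_layout()) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (nrow(pixels) %% 2L != 0L || ncol(pixels) %% 2L != 0L)
    stop("mosaic dimensions must be even (2x2 superpixels)", call. = FALSE)
  check_layout(layout)
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxval))
    stop(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                 maxval, bit_depth), call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 layout = layout),
            class = "raw_mosaic")
}

#' @export
print.raw_mosaic <- function(x, ...) {
  cat(sprintf("raw_mosaic: %d x %d px, %d-bit, layout [[%g,%g],[%g,%g]]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$layout[1, 1], x$layout[1, 2], x$layout[2, 1], x$layout[2, 2]))
  invisible(x)
}

#' Split a DoFP mosaic into its four polarizer-angle images
#'
#' Extracts the 0/45/90/135-degree subpixel images using non-overlapping
#' 2x2 superpixels, so each output pixel corresponds to one superpixel and
#' the outputs have half the mosaic's dimensions. No interpolation is
#' performed.
#'
#' @param mosaic A [raw_mosaic()].
#' @return A list with matrices `I0`, `I45`, `I90`, `I135`.
#' @export
demosaic <- function(mosaic) {
  stopifnot(inherits(mosaic, "raw_mosaic"))
  px <- mosaic$pixels
  out <- list()
  for (dr in 1:2) for (dc in 1:2) {
    ang <- mosaic$layout[dr, dc]
    out[[paste0("I", ang)]] <-
      px[seq(dr, nrow(px), by = 2L), seq(dc, ncol(px), by = 2L), drop = FALSE]
  }
  out[c("I0", "I45", "I90", "I135")]
}

#' Interleave four polarizer-angle images back into a mosaic
#'
#' Inverse of [demosaic()]; mainly used to verify that demosaicking is a
#' lossless rearrangement.
#'
#' @param imgs List with matrices `I0`, `I45`, `I90`, `I135`.
#' @param layout 2x2 polarizer layout.
#' @return A matrix of doubled dimensions.
#' @export
interleave <- function(imgs, layout = default_layout()) {
  check_layout(layout)
  h <- nrow(imgs$I0); w <- ncol(imgs$I0)
  px <- matrix(0, 2L * h, 2L * w)
  for (dr in 1:2) for (dc in 1:2) {
    ang <- layout[dr, dc]
    px[seq(dr, 2L * h, by = 2L), seq(dc, 2L * w, by = 2L)] <-
      imgs[[paste0("I", ang)]]
  }
  px
}

#' Compute linear Stokes parameters from the four polarizer images
#'
#' Uses the pairwise-difference convention: `S0 = (I0+I45+I90+I135)/2`,
#' `S1 = I0 - I90`, `S2 = I45 - I135`. With ideal polarizers transmitting
#' half of unpolarized light, this S0 equals the scene intensity, matching
#' the Malus-law forward model `I_phi = 0.5 (S0 + S1 cos 2phi + S2 sin 2phi)`.
#'
#' @param I0,I45,I90,I135 Matrices of identical shape (counts).
#' @return An object of class `stokes_image` with fields `S0`, `S1`, `S2`.
#' @export
compute_stokes <- function(I0, I45, I90, I135) {
  dims <- dim(I0)
  if (!identical(dims, dim(I45)) || !identical(dims, dim(I90)) ||
      !identical(dims, dim(I135)))
    stop("the four polarizer images must have identical dimensions",
         call. = FALSE)
  structure(list(S0 = (I0 + I45 + I90 + I135) / 2,
                 S1 = I0 - I90,
                 S2 = I45 - I135),
            class = "stokes_image")
}

wrap_aop <- function(a) ((a + 90) %% 180) - 90

#' Degree and angle of polarization maps with exposure masking
#'
#' Converts a Stokes image into the degree of linear polarization
#' `DoP = sqrt(S1^2 + S2^2) / S0` (clipped to `[0, 1]`; values above 1 can
#' arise from noise and are counted), the angle of polarization
#' `AoP = 0.5 atan2(S2, S1)` in degrees wrapped to `[-90, 90)` with 0 degrees
#' horizontal, and an exposure mask. A superpixel is flagged overexposed when
#' any of its four subpixels reaches `2^bit_depth - 1 - saturation_margin`,
#' and underexposed when `S0 <= floor_threshold`; DoP/AoP are undefined there.
#' At DoP = 0 the AoP is mathematically undefined; by convention it is
#' reported as 0 degrees, and pixels with DoP < 0.01 should be excluded from
#' AoP summary statistics.
#'
#' @param stokes A `stokes_image`.
#' @param mosaic Optionally the originating [raw_mosaic()]; required for
#'   overexposure detection (it needs the raw subpixel values).
#' @param saturation_margin Counts below full scale still treated as
#'   saturated (default 0: only full-scale counts).
#' @param floor_threshold S0 at or below this (counts) is underexposed.
#' @return Object of class `polarization_maps` with fields `dop`, `aop`,
#'   `intensity` (= S0), `mask` (character matrix, one of `"valid"`,
#'   `"overexposed"`, `"underexposed"`) and attribute `n_clipped`
#'   (count of DoP values clipped down to 1).
#' @export
dop_aop <- function(stokes, mosaic = NULL, saturation_margin = 0,
                    floor_threshold = 1) {
  stopifnot(inherits(stokes, "stokes_image"))
  S0 <- stokes$S0; S1 <- stokes$S1; S2 <- stokes$S2
  dop <- matrix(0, nrow(S0), ncol(S0))
  ok <- S0 > floor_threshold
  dop[ok] <- sqrt(S1[ok]^2 + S2[ok]^2) / S0[ok]
  n_clipped <- sum(dop > 1)
  dop[dop > 1] <- 1
  aop <- wrap_aop(0.5 * atan2(S2, S1) * 180 / pi)
  aop[S1 == 0 & S2 == 0] <- 0

  mask <- matrix("valid", nrow(S0), ncol(S0))
  mask[S0 <= floor_threshold] <- "underexposed"
  if (!is.null(mosaic)) {
    stopifnot(inherits(mosaic, "raw_mosaic"))
    sat <- 2^mosaic$bit_depth - 1 - saturation_margin
    sub <- demosaic(mosaic)
    submax <- pmax(sub$I0, sub$I45, sub$I90, sub$I135)
    if (!identical(dim(submax), dim(S0)))
      stop("mosaic and stokes image dimensions do not match", call. = FALSE)
    mask[submax >= sat] <- "overexposed"
  }
  structure(list(dop = dop, aop = aop, intensity = S0, mask = mask),
            class = "polarization_maps", n_clipped = n_clipped)
}

#' @export
print.polarization_maps <- function(x, ...) {
  v <- x$mask == "valid"
  cat(sprintf(
    "polarization_maps: %d x %d, %.1f%% valid, mean DoP %.3f (valid px), %d clipped\n",
    nrow(x$dop), ncol(x$dop), 100 * mean(v),
    if (any(v)) mean(x$dop[v]) else NA_real_, attr(x, "n_clipped")))
  invisible(x)
}

# colour lookup helpers: 256-entry RGB tables in [0,1]
seq_cmap <- function() t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255)
cyc_cmap <- function() t(grDevices::col2rgb(grDevices::hsv(seq(0, 255) / 256, 0.9, 0.9)) / 255)

#' Render a polarization map as an 8-bit false-colour image
#'
#' DoP is mapped linearly on `[0, 1]` to a sequential (viridis) colormap,
#' AoP on `[-90, 90)` to a cyclic hue wheel (so -90 and +90 meet smoothly),
#' and intensity to linear greyscale. In the DoP and AoP channels,
#' overexposed pixels are painted white and underexposed pixels black.
#'
#' @param maps A `polarization_maps` object.
#' @param channel One of `"dop"`, `"aop"`, `"intensity"`.
#' @return Integer array `height x width x 3` with values in 0..255.
#' @export
render_false_colour <- function(maps, channel = c("dop", "aop", "intensity")) {
  stopifnot(inherits(maps, "polarization_maps"))
  channel <- match.arg(channel)
  h <- nrow(maps$dop); w <- ncol(maps$dop)
  if (channel == "intensity") {
    g <- maps$intensity / max(maps$intensity, 1)
    idx <- pmin(pmax(round(g * 255), 0), 255)
    rgb01 <- cbind(idx, idx, idx) / 255
  } else if (channel == "dop") {
    idx <- pmin(pmax(round(maps$dop * 255), 0), 255)
    rgb01 <- seq_cmap()[idx + 1L, , drop = FALSE]
  } else {
    frac <- (wrap_aop(maps$aop) + 90) / 180   # [0, 1)
    idx <- pmin(floor(frac * 256), 255)
    rgb01 <- cyc_cmap()[idx + 1L, , drop = FALSE]
  }
  if (channel %in% c("dop", "aop")) {
    over <- as.vector(maps$mask == "overexposed")
    under <- as.vector(maps$mask == "underexposed")
    rgb01[over, ] <- 1
    rgb01[under, ] <- 0
  }
  img <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) img[, , k] <- as.integer(round(matrix(rgb01[, k], h, w) * 255))
  img
}

#' Read a mosaic image from TIFF or PNG
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @param bit_depth Sensor bit depth used to scale/validate the counts.
#' @param layout 2x2 polarizer layout.
#' @return A [raw_mosaic()].
#' @export
read_mosaic <- function(path, bit_depth = 12L, layout = default_layout()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    px <- round(px * (2^bit_depth - 1))   # png gives [0,1]
  } else stop("unsupported mosaic format: ", ext, call. = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  raw_mosaic(px, bit_depth = bit_depth, layout = layout)
}

#' Write a mosaic or false-colour image
#'
#' Mosaics are written as single-channel TIFF with their counts scaled to
#' `[0, 1]` (the standard float-TIFF convention); false-colour arrays as
#' 8-bit PNG.
#'
#' @param x A `raw_mosaic`, or an integer `h x w x 3` array from
#'   [render_false_colour()].
#' @param path Output path (`.tiff` for mosaics, `.png` for colour images).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "raw_mosaic")) {
    tiff::writeTIFF(x$pixels / (2^x$bit_depth - 1), path, bits.per.sample = 16L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    png::writePNG(x / 255, path)
  } else stop("cannot write object of this type", call. = FALSE)
  invisible(path)
}

#' Read a YAML polarimetry/pipeline configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
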