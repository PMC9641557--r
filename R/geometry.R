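# Experiment geometry: PONI-convention detector calibration, the map from
# sub-pixel detector coordinates to polar (2theta, chi), and the sub-pixel
# level intensity corrections.

#' Detector/beam geometry
#'
#' Describes a flat area detector in the PONI (point of normal incidence)
#' convention: the sample sits at the origin, the direct beam travels along
#' the lab third axis, and `distance` is measured from the sample to the PONI
#' along the detector normal. `poni1`/`poni2` locate the PONI on the detector
#' in metres along the slow (row) and fast (column) axes, measured from the
#' detector edge. `rot1`, `rot2`, `rot3` tilt the detector about the lab
#' axes (slow, fast, beam), applied in that order.
#'
#' Pixel coordinates are pixel-centred and 0-based throughout: pixel
#' `(m, n)` spans `[m - 0.5, m + 0.5] x [n - 0.5, n + 0.5]` in pixel units,
#' so its centre in metres along the slow axis is `(m + 0.5) * pixel1`.
#'
#' @param distance Sample-to-detector distance along the detector normal (m).
#' @param poni1,poni2 PONI coordinates on the detector (m), slow then fast axis.
#' @param rot1,rot2,rot3 Detector rotations (rad); default 0 (orthogonal setup).
#' @param wavelength X-ray wavelength (m).
#' @param pixel1,pixel2 Pixel pitch along the slow/fast axes (m).
#' @param shape Integer vector `c(n_rows, n_cols)` of the detector.
#' @return An object of class `"geometry"`.
#' @export
geometry <- function(distance, poni1, poni2, rot1 = 0, rot2 = 0, rot3 = 0,
                     wavelength, pixel1, pixel2, shape) {
  stopifnot(is.numeric(distance), length(distance) == 1L)
  if (distance <= 0) stop("`distance` must be > 0, got ", distance)
  if (pixel1 <= 0 || pixel2 <= 0) stop("pixel pitches must be > 0")
  if (wavelength <= 0) stop("`wavelength` must be > 0")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L) || anyNA(shape))
    stop("`shape` must be two positive integers (n_rows, n_cols)")
  structure(
    list(distance = distance, poni1 = poni1, poni2 = poni2,
         rot1 = rot1, rot2 = rot2, rot3 = rot3,
         wavelength = wavelength, pixel1 = pixel1, pixel2 = pixel2,
         shape = shape),
    class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry> ", x$shape[1], "x", x$shape[2], " px, pitch ",
      format(x$pixel1 * 1e6), "x", format(x$pixel2 * 1e6), " um\n",
      "  distance ", format(x$distance), " m, wavelength ",
      format(x$wavelength * 1e10), " A\n",
      "  PONI (", format(x$poni1), ", ", format(x$poni2), ") m, rotations (",
      format(x$rot1), ", ", format(x$rot2), ", ", format(x$rot3), ") rad\n",
      sep = "")
  invisible(x)
}

# rotation matrix of the tilted detector: columns are the detector slow, fast
# and normal axes expressed in the lab frame (R = R3 %*% R2 %*% R1)
.geom_rotation <- function(geom) {
  c1 <- cos(geom$rot1); s1 <- sin(geom$rot1)
  c2 <- cos(geom$rot2); s2 <- sin(geom$rot2)
  c3 <- cos(geom$rot3); s3 <- sin(geom$rot3)
  R1 <- matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  R2 <- matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3)
  R3 <- matrix(c(c3, s3, 0, -s3, c3, 0, 0, 0, 1), 3, 3)
  R3 %*% R2 %*% R1
}

#' Polar coordinates of sub-pixel centres
#'
#' Maps sub-pixel centre coordinates (in pixel units, possibly fractional)
#' to the scattering angle 2\eqn{\theta} and the azimuth \eqn{\chi} around
#' the direct beam. A detector point at `(r, c)` pixel units sits at
#' `(r + 0.5) * pixel1 - poni1` / `(c + 0.5) * pixel2 - poni2` metres from
#' the PONI in the detector plane; the lab-frame ray is that in-plane offset
#' rotated by the detector tilts plus `distance` along the detector normal.
#'
#' Azimuth convention: \eqn{\chi = 0} along the detector +column (fast) axis,
#' increasing towards the +row (slow) axis, reported in degrees wrapped to
#' `[0, 360)`. At the PONI itself \eqn{\chi} is undefined and reported as 0.
#'
#' @param geom A [geometry()].
#' @param row_centers,col_centers Numeric vectors of sub-pixel centre
#'   coordinates in pixel units (0-based, pixel-centred; recycled together).
#' @return A list with numeric vectors `two_theta` and `chi`, both in degrees.
#' @export
subpixel_polar <- function(geom, row_centers, col_centers) {
  n <- max(length(row_centers), length(col_centers))
  r <- rep_len(as.numeric(row_centers), n)
  c_ <- rep_len(as.numeric(col_centers), n)
  p1 <- (r + 0.5) * geom$pixel1 - geom$poni1
  p2 <- (c_ + 0.5) * geom$pixel2 - geom$poni2
  R <- .geom_rotation(geom)
  # v = R %*% c(p1, p2, L), vectorised
  v1 <- R[1, 1] * p1 + R[1, 2] * p2 + R[1, 3] * geom$distance
  v2 <- R[2, 1] * p1 + R[2, 2] * p2 + R[2, 3] * geom$distance
  v3 <- R[3, 1] * p1 + R[3, 2] * p2 + R[3, 3] * geom$distance
  rho <- sqrt(v1^2 + v2^2)
  tt <- atan2(rho, v3) * 180 / pi
  chi <- ifelse(rho == 0, 0, atan2(v1, v2) * 180 / pi) %% 360
  list(two_theta = tt, chi = chi)
}

#' Sub-pixel intensity correction factors
#'
#' Multiplicative correction evaluated per sub-pixel (not per pixel), the
#' product of the enabled factors:
#' \describe{
#'   \item{solid angle}{\eqn{\cos^3\alpha} with \eqn{\alpha} the incidence
#'     angle of the scattered ray on the detector plane; normalised so an
#'     orthogonal detector has factor 1 at \eqn{2\theta = 0}.}
#'   \item{polarization}{Kahn-type factor for a horizontally polarized beam
#'     with polarization fraction `p`:
#'     \eqn{p(1 - \sin^2 2\theta \cos^2\chi) + (1-p)(1 - \sin^2 2\theta \sin^2\chi)}.}
#'   \item{Lorentz}{\eqn{1/\sin 2\theta} shape for texture work, normalised
#'     to 1 at (and clamped below) a small-angle floor so the forward-beam
#'     limit stays finite: \eqn{\sin(2\theta_f)/\sin(\max(2\theta, 2\theta_f))}.
#'     Off by default.}
#' }
#' With every flag off the factor is identically 1.
#'
#' @param geom A [geometry()].
#' @param coords Polar coordinates as returned by [subpixel_polar()].
#' @param solid_angle Logical; apply the solid-angle factor.
#' @param polarization `NULL` (off) or the horizontal polarization fraction
#'   `p` in `[0, 1]` (0.99 is synchrotron-typical).
#' @param lorentz Logical; apply the Lorentz factor (off by default — it is
#'   specific to texture-style analyses).
#' @param lorentz_floor Guard floor for the Lorentz factor, in degrees 2theta.
#' @return Numeric vector of multiplicative weights, one per coordinate.
#' @export
correction_factor <- function(geom, coords, solid_angle = FALSE,
                              polarization = NULL, lorentz = FALSE,
                              lorentz_floor = 1) {
  tt <- coords$two_theta * pi / 180
  f <- rep(1, length(tt))
  if (isTRUE(solid_angle)) {
    # cos(alpha) = unit ray . detector normal; the ray in lab frame is
    # (sin tt sin chi, sin tt cos chi, cos tt) by the chi convention above
    chi <- coords$chi * pi / 180
    nrm <- .geom_rotation(geom)[, 3]
    ca <- sin(tt) * sin(chi) * nrm[1] + sin(tt) * cos(chi) * nrm[2] +
      cos(tt) * nrm[3]
    f <- f * pmax(ca, 0)^3
  }
  if (!is.null(polarization)) {
    p <- polarization
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
      stop("polarization fraction must be a single value in [0, 1]")
    chi <- coords$chi * pi / 180
    s2 <- sin(tt)^2
    f <- f * (p * (1 - s2 * cos(chi)^2) + (1 - p) * (1 - s2 * sin(chi)^2))
  }
  if (isTRUE(lorentz)) {
    fl <- lorentz_floor * pi / 180
    f <- f * sin(fl) / sin(pmax(tt, fl))
  }
  f
}

#' Read a PONI calibration file
#'
#' Parses the `key: value` PONI text dialect (keys `Distance`, `Poni1`,
#' `Poni2`, `Rot1`-`Rot3`, `Wavelength`, pixel pitches either as
#' `PixelSize1`/`PixelSize2` or inside a JSON `Detector_config`). Keys are
#' matched case-insensitively; absent rotations default to 0. The detector
#' shape is taken from `Detector_config` (`max_shape`) when present, else
#' from the `shape` argument.
#'
#' @param path Path to the PONI file.
#' @param shape Optional `c(n_rows, n_cols)`, required when the file does not
#'   declare the detector shape.
#' @return A [geometry()].
#' @export
load_poni <- function(path, shape = NULL) {
  if (!file.exists(path)) stop("PONI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hit <- regexpr(":", lines, fixed = TRUE)
  keys <- tolower(trimws(substr(lines, 1L, hit - 1L)))
  vals <- trimws(substring(lines, hit + 1L))
  names(vals) <- keys
  getnum <- function(key, default = NULL) {
    if (key %in% keys) {
      x <- suppressWarnings(as.numeric(vals[[key]]))
      if (is.na(x)) stop("PONI key `", key, "` is not numeric: ", vals[[key]])
      x
    } else if (is.null(default)) {
      stop("PONI file is missing mandatory key `", key, "`")
    } else default
  }
  px1 <- NULL; px2 <- NULL
  if ("detector_config" %in% keys) {
    cfg <- jsonlite::fromJSON(vals[["detector_config"]])
    if (!is.null(cfg$pixel1)) px1 <- cfg$pixel1
    if (!is.null(cfg$pixel2)) px2 <- cfg$pixel2
    if (is.null(shape) && !is.null(cfg$max_shape)) shape <- cfg$max_shape
  }
  if ("pixelsize1" %in% keys) px1 <- getnum("pixelsize1")
  if ("pixelsize2" %in% keys) px2 <- getnum("pixelsize2")
  if (is.null(px1) || is.null(px2))
    stop("PONI file is missing mandatory key `pixelsize1`/`pixelsize2` ",
         "(and no pixel pitch in Detector_config)")
  if (is.null(shape))
    stop("detector shape is neither in the PONI file nor given via `shape`")
  geometry(distance = getnum("distance"),
           poni1 = getnum("poni1"), poni2 = getnum("poni2"),
           rot1 = getnum("rot1", 0), rot2 = getnum("rot2", 0),
           rot3 = getnum("rot3", 0),
           wavelength = getnum("wavelength"),
           pixel1 = px1, pixel2 = px2, shape = shape)
}

#' Write a PONI calibration file
#'
#' Emits the same `key: value` dialect [load_poni()] reads, including a JSON
#' `Detector_config` carrying the pixel pitch and detector shape so a
#' round trip reproduces the geometry exactly.
#'
#' @param geom A [geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poni <- function(geom, path) {
  fmt <- function(x) format(x, digits = 17, scientific = TRUE)
  cfg <- jsonlite::toJSON(
    list(pixel1 = geom$pixel1, pixel2 = geom$pixel2,
         max_shape = geom$shape),
    auto_unbox = TRUE, digits = NA)
  writeLines(c(
    "# PONI calibration",
    "poni_version: 2",
    paste0("Detector_config: ", cfg),
    paste0("Distance: ", fmt(geom$distance)),
    paste0("Poni1: ", fmt(geom$poni1)),
    paste0("Poni2: ", fmt(geom$poni2)),
    paste0("Rot1: ", fmt(geom$rot1)),
    paste0("Rot2: ", fmt(geom$rot2)),
    paste0("Rot3: ", fmt(geom$rot3)),
    paste0("Wavelength: ", fmt(geom$wavelength))), path)
  invisible(path)
}

# short stable fingerprint of a geometry for transform metadata
.geom_fingerprint <- function(geom) {
  paste(formatC(c(geom$distance, geom$poni1, geom$poni2, geom$rot1,
                  geom$rot2, geom$rot3, geom$wavelength, geom$pixel1,
                  geom$pixel2, geom$shape), format = "g", digits = 15),
        collapse = "|")
}
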