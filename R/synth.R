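# Synthetic detector frames with known ground truth: Eiger-like geometry,
# Debye-Scherrer rings with azimuthally modulated (textured) intensity,
# Poisson counting noise, masked gaps and hot pixels.

#' Default synthetic-experiment geometry
#'
#' A compact Eiger-like setup: 256 x 256 pixels of 75 um pitch, 0.04 m
#' sample-detector distance, 17 keV beam (wavelength 0.7293 A), beam
#' centred on the detector. The short distance keeps the hydroxyapatite
#' (002) reflection (d = 3.44 A, 2theta ~ 12.2 deg, radius ~ 115 px here)
#' on-detector and the ~15 deg HAP multiplet near the corners. All values
#' are overridable.
#'
#' @param shape Detector shape `c(n_rows, n_cols)`.
#' @param distance,pixel,energy_keV Setup parameters.
#' @return A [geometry()].
#' @export
synthetic_geometry <- function(shape = c(256L, 256L), distance = 0.04,
                               pixel = 75e-6, energy_keV = 17) {
  wavelength <- 12.3984193 / energy_keV * 1e-10
  geometry(distance = distance,
           poni1 = shape[1] / 2 * pixel, poni2 = shape[2] / 2 * pixel,
           wavelength = wavelength, pixel1 = pixel, pixel2 = pixel,
           shape = shape)
}

#' Describe a synthetic diffraction ring
#'
#' A ring has a Gaussian radial profile centred at `two_theta` with width
#' `radial_sigma`, modulated azimuthally by the same two-lobe circular
#' Gaussian model the texture fit assumes (so recovery tests are closed
#' loop), or by a von Mises lobe pair to probe model misspecification.
#'
#' @param two_theta Ring centre (deg).
#' @param radial_sigma Radial Gaussian width (deg).
#' @param B0,A1,A2,chi0,sigma_chi Azimuthal model parameters: isotropic
#'   level, the two lobe amplitudes, the preferred azimuth (deg) and lobe
#'   width (deg). `A1 = A2 = 0` gives an isotropic ring of level `B0`.
#' @param azimuthal_model `"gaussian"` (default, matches the fit model) or
#'   `"vonmises"`.
#' @return A `"ring_spec"` list.
#' @export
ring_spec <- function(two_theta, radial_sigma = 0.25, B0 = 0, A1 = 0, A2 = 0,
                      chi0 = 0, sigma_chi = 15,
                      azimuthal_model = c("gaussian", "vonmises")) {
  azimuthal_model <- match.arg(azimuthal_model)
  stopifnot(two_theta > 0, radial_sigma > 0, sigma_chi > 0,
            B0 >= 0, A1 >= 0, A2 >= 0)
  structure(list(two_theta = two_theta, radial_sigma = radial_sigma,
                 B0 = B0, A1 = A1, A2 = A2, chi0 = chi0,
                 sigma_chi = sigma_chi, azimuthal_model = azimuthal_model),
            class = "ring_spec")
}

.ring_azimuthal <- function(ring, chi) {
  if (ring$azimuthal_model == "gaussian") {
    .azimuthal_model(chi, ring$B0, ring$A1, ring$A2, ring$chi0,
                     ring$sigma_chi)
  } else {
    kappa <- 1 / (ring$sigma_chi * pi / 180)^2
    dd <- (chi - ring$chi0) * pi / 180
    ring$B0 + ring$A1 * exp(kappa * (cos(dd) - 1)) +
      ring$A2 * exp(kappa * (cos(dd - pi) - 1))
  }
}

#' Describe a synthetic detector frame
#'
#' @param geometry A [geometry()]; default [synthetic_geometry()].
#' @param rings List of [ring_spec()]s.
#' @param background_level Flat detector background (counts).
#' @param poisson Sample Poisson counting noise around the expectation.
#' @param hot_pixels `NULL` or a data frame/matrix with columns `m`, `n`
#'   (0-based pixel indices) and `value`, overwritten into the frame last.
#' @param mask Logical detector mask (`TRUE` = data); masked pixels read 0.
#' @param seed RNG seed; a fixed seed makes the frame bit-reproducible.
#' @return A `"frame_scene"` list.
#' @export
frame_scene <- function(geometry = synthetic_geometry(), rings = list(),
                        background_level = 0, poisson = FALSE,
                        hot_pixels = NULL, mask = NULL, seed = NULL) {
  stopifnot(background_level >= 0)
  if (length(rings) && inherits(rings, "ring_spec")) rings <- list(rings)
  structure(list(geometry = geometry, rings = rings,
                 background_level = background_level, poisson = poisson,
                 hot_pixels = hot_pixels, mask = mask, seed = seed),
            class = "frame_scene")
}

#' Render a synthetic frame with its ground truth
#'
#' Evaluates, at every pixel centre's polar coordinates, the expected
#' intensity `background + sum over rings of radial Gaussian x azimuthal
#' model`, optionally draws Poisson counts around it under the scene seed,
#' overwrites hot pixels last, and zeroes masked pixels. The returned ground
#' truth carries each ring's parameters and analytic degree of orientation,
#' so downstream recovery tests have an exact reference.
#'
#' @param scene A [frame_scene()].
#' @return List: `counts` (matrix), `expected` (noise-free expectation,
#'   before hot pixels/mask), `truth` (per-ring parameters + analytic
#'   `doo`), `scene`.
#' @export
render_frame <- function(scene) {
  stopifnot(inherits(scene, "frame_scene"))
  geom <- scene$geometry
  m_max <- geom$shape[1]; n_max <- geom$shape[2]
  rows <- rep(seq_len(m_max) - 1L, times = n_max)
  cols <- rep(seq_len(n_max) - 1L, each = m_max)
  pol <- subpixel_polar(geom, rows, cols)
  expected <- rep(scene$background_level, m_max * n_max)
  for (ring in scene$rings) {
    radial <- exp(-(pol$two_theta - ring$two_theta)^2 /
                    (2 * ring$radial_sigma^2))
    expected <- expected + radial * .ring_azimuthal(ring, pol$chi)
  }
  expected <- matrix(expected, m_max, n_max)
  counts <- expected
  if (isTRUE(scene$poisson)) {
    if (!is.null(scene$seed)) set.seed(scene$seed)
    counts <- matrix(stats::rpois(length(expected), expected), m_max, n_max)
  }
  if (!is.null(scene$hot_pixels)) {
    hp <- as.data.frame(scene$hot_pixels)
    counts[cbind(hp$m + 1L, hp$n + 1L)] <- hp$value
  }
  if (!is.null(scene$mask)) counts[!scene$mask] <- 0
  truth <- lapply(scene$rings, function(ring)
    c(unclass(ring),
      .orientation_densities(ring$B0, ring$A1, ring$A2, ring$sigma_chi)["doo"]))
  list(counts = counts, expected = expected, truth = truth, scene = scene)
}

#' Write a grid of scenes as an HDF5 frame-stack file set
#'
#' Renders every scene of a scan grid and writes the frames, in scan order,
#' split across HDF5 files of `frames_per_file` frames each (the last file
#' ragged), in the same dialect [integrate_file()] reads
#' (`entry/data/data`, integer counts). Ground truth and the scan layout go
#' to a JSON sidecar next to the files.
#'
#' @param scenes List of [frame_scene()]s in scan order (lateral axis
#'   fastest); an attribute or argument `grid_shape` records the layout.
#' @param path Output directory (created if needed).
#' @param frames_per_file Frames per HDF5 file.
#' @param grid_shape Optional `c(n_lateral, n_slow)` recorded in the
#'   sidecar.
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest: file paths, frames per file, sidecar
#'   path.
#' @export
write_scan_dataset <- function(scenes, path, frames_per_file = 20L,
                               grid_shape = NULL, prefix = "scan") {
  stopifnot(length(scenes) >= 1L)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  n <- length(scenes)
  starts <- seq(1L, n, by = as.integer(frames_per_file))
  files <- character(length(starts))
  shape <- scenes[[1]]$geometry$shape
  truth <- vector("list", n)
  for (f in seq_along(starts)) {
    idx <- starts[f]:min(starts[f] + frames_per_file - 1L, n)
    stack <- array(0L, dim = c(shape, length(idx)))
    for (k in seq_along(idx)) {
      fr <- render_frame(scenes[[idx[k]]])
      stack[, , k] <- as.integer(round(fr$counts))
      truth[[idx[k]]] <- fr$truth
    }
    files[f] <- file.path(path, sprintf("%s_%05d.h5", prefix, f))
    if (file.exists(files[f])) unlink(files[f])
    rhdf5::h5createFile(files[f])
    rhdf5::h5createGroup(files[f], "entry")
    rhdf5::h5createGroup(files[f], "entry/data")
    rhdf5::h5write(stack, files[f], "entry/data/data")
    rhdf5::h5closeAll()
  }
  sidecar <- file.path(path, paste0(prefix, "_truth.json"))
  jsonlite::write_json(
    list(n_frames = n, frames_per_file = frames_per_file,
         grid_shape = grid_shape, scan_order = "lateral-fastest",
         files = basename(files),
         frames = lapply(truth, function(tr) tr)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(files = files, sidecar = sidecar,
                 frames_per_file = diff(c(starts, n + 1L))))
}
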