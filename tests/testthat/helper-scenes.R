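# Shared fixtures: small geometries, synthetic azimuthal profiles and
# analytically constructed cakes, all generated in code.

# small centred untilted detector; 2theta at the edge midpoint is
# atan(shape/2 * pixel / distance)
tiny_geometry <- function(shape = c(32L, 32L), distance = 0.1,
                          pixel = 1e-4, ...) {
  geometry(distance = distance,
           poni1 = shape[1] / 2 * pixel, poni2 = shape[2] / 2 * pixel,
           wavelength = 1e-10, pixel1 = pixel, pixel2 = pixel,
           shape = shape, ...)
}

two_theta_edge <- function(geom) {
  atan(min(geom$shape) / 2 * geom$pixel1 / geom$distance) * 180 / pi
}

two_theta_corner <- function(geom) {
  atan(sqrt(sum((geom$shape / 2)^2)) * geom$pixel1 / geom$distance) * 180 / pi
}

# azimuthal profile drawn from the two-lobe circular Gaussian model
make_profile <- function(B0, A1, A2, chi0, sigma, n_bins = 72,
                         noise_sd = 0, seed = NULL) {
  chi <- seq(0, 360, length.out = n_bins + 1L)[-(n_bins + 1L)] +
    180 / n_bins
  y <- B0 +
    A1 * exp(-circular_distance(chi, chi0)^2 / (2 * sigma^2)) +
    A2 * exp(-circular_distance(chi, chi0 + 180)^2 / (2 * sigma^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n_bins, sd = noise_sd)
  }
  structure(list(chi_centers = chi, intensity = y,
                 valid = rep(TRUE, n_bins)),
            class = "azimuthal_profile")
}

# cake matrix built directly from an analytic model: flat diffuse ramp in
# 2theta plus one Gaussian ridge whose area varies with chi
make_cake_matrix <- function(radial, n_azi, peak_tt, peak_sigma,
                             area_of_chi, ramp = c(0, 0)) {
  chi <- seq(0, 360, length.out = n_azi + 1L)[-(n_azi + 1L)] + 180 / n_azi
  I <- outer(ramp[1] + ramp[2] * radial, rep(1, n_azi))
  amp <- area_of_chi(chi) / (peak_sigma * sqrt(2 * pi))
  I <- I + exp(-(radial - peak_tt)^2 / (2 * peak_sigma^2)) %o% amp
  I
}
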