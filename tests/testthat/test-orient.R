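test_that("background subtraction cancels a cake that is flat in 2theta", {
  radial <- seq(10.05, 13.95, by = 0.1)
  n_azi <- 36
  # flat in 2theta at every chi, but chi-dependent level
  I <- matrix(1, length(radial), 1) %*% t(5 + 3 * sin(seq_len(n_azi)))
  pr <- extract_profile(I, peak_window = c(11.5, 12.5),
                        bg_windows = list(c(10.5, 11.3), c(12.7, 13.5)),
                        radial = radial)
  expect_true(all(pr$valid))
  expect_true(all(abs(pr$intensity) < 1e-10))
})

test_that("a Gaussian ridge on a sloping background is recovered area-for-area", {
  radial <- seq(10.005, 13.995, by = 0.01)
  n_azi <- 72
  chi <- seq(0, 360, length.out = n_azi + 1L)[-(n_azi + 1L)] + 180 / n_azi
  area <- 40 + 25 * cos(2 * chi * pi / 180)^2
  I <- make_cake_matrix(radial, n_azi, peak_tt = 12, peak_sigma = 0.12,
                        area_of_chi = function(ch) 40 + 25 * cos(2 * ch * pi / 180)^2,
                        ramp = c(30, -1.5))
  pr <- extract_profile(I, peak_window = c(11.2, 12.8),
                        bg_windows = list(c(10.2, 11.0), c(13.0, 13.8)),
                        radial = radial)
  expect_true(all(pr$valid))
  expect_lt(max(abs(pr$intensity - area) / area), 0.01)
})

test_that("NaN cake bins invalidate the corresponding profile bins", {
  radial <- seq(10.05, 13.95, by = 0.1)
  I <- matrix(10, length(radial), 12)
  I[radial > 11.5 & radial < 12.5, 4] <- NaN
  pr <- extract_profile(I, peak_window = c(11.5, 12.5),
                        bg_windows = list(c(10.5, 11.3), c(12.7, 13.5)),
                        radial = radial)
  expect_false(pr$valid[4])
  expect_true(all(pr$valid[-4]))
  expect_error(extract_profile(I, peak_window = c(20, 21),
                               bg_windows = list(c(10.5, 11.3), c(12.7, 13.5)),
                               radial = radial), "empty")
})

test_that("the chord distance is periodic, symmetric and linear for small angles", {
  expect_identical(circular_distance(40, 40), 0)
  expect_equal(circular_distance(77 + 360, 77), 0, tolerance = 1e-12)
  expect_equal(circular_distance(10, 350), circular_distance(350, 10))
  expect_equal(circular_distance(10, 350), (360 / pi) * sin(10 * pi / 180),
               tolerance = 1e-12)
  small <- c(0.1, 0.5, 2)
  expect_equal(circular_distance(small, 0), small, tolerance = 1e-3)
  # maximal for angles 180 deg apart
  expect_equal(circular_distance(200, 20), 360 / pi, tolerance = 1e-12)
})

test_that("a noiseless model profile is recovered to solver precision", {
  pr <- make_profile(B0 = 5, A1 = 20, A2 = 15, chi0 = 30, sigma = 12)
  fit <- fit_orientation(pr)
  expect_lt(fit$rss, 1e-16)
  expect_equal(fit$chi0, 30, tolerance = 1e-5)
  expect_equal(fit$sigma, 12, tolerance = 1e-5)
  expect_equal(fit$A1, 20, tolerance = 1e-5)
  expect_equal(fit$A2, 15, tolerance = 1e-5)
  expect_equal(fit$B0, 5, tolerance = 1e-4)
  expect_true(fit$ok)
})

test_that("parameters are recovered from a noisy profile at documented accuracy", {
  pr <- make_profile(B0 = 5, A1 = 20, A2 = 15, chi0 = 30, sigma = 12,
                     noise_sd = 0.5, seed = 42)
  fit <- fit_orientation(pr)
  expect_lt(abs(fit$chi0 - 30), 1)
  expect_lt(abs(fit$sigma - 12), 1)
  expect_lt(abs(fit$A1 - 20) / 20, 0.05)
  expect_lt(abs(fit$A2 - 15) / 15, 0.05)
})

test_that("pure background yields no orientation", {
  pr <- make_profile(B0 = 8, A1 = 0, A2 = 0, chi0 = 0, sigma = 12,
                     noise_sd = 0.1, seed = 7)
  fit <- fit_orientation(pr)
  expect_true(!fit$ok || fit$doo < 0.05)
})

test_that("fitting is equivariant under azimuthal shifts and scale-invariant in DoO", {
  base <- make_profile(B0 = 4, A1 = 18, A2 = 12, chi0 = 50, sigma = 15,
                       noise_sd = 0.3, seed = 9)
  fit0 <- fit_orientation(base)
  for (shift in c(40, 100)) {
    shifted <- base
    n <- length(base$intensity)
    k <- shift / (360 / n)          # whole bins
    shifted$intensity <- base$intensity[((seq_len(n) - 1 - k) %% n) + 1]
    fit_s <- fit_orientation(shifted)
    d <- abs(fit_s$chi0 - ((fit0$chi0 + shift) %% 180))
    expect_lt(min(d, 180 - d), 0.5)
    expect_equal(fit_s$sigma, fit0$sigma, tolerance = 0.05)
  }
  scaled <- base
  scaled$intensity <- base$intensity * 13
  expect_equal(fit_orientation(scaled)$doo, fit0$doo, tolerance = 1e-3)
})

test_that("degree of orientation follows the lobe-area/background-area closed form", {
  f <- list(B0 = 1, A1 = 10, A2 = 10, sigma = 10)
  d <- degree_of_orientation(f)
  expect_equal(d$doo, sqrt(2 * pi) * 10 * 20 /
                 (sqrt(2 * pi) * 10 * 20 + 360), tolerance = 1e-12)
  expect_equal(d$doo, 0.582, tolerance = 1e-3)
  # numerical cross-check: lobe area over the circle vs background area
  chi <- seq(0, 360, length.out = 100001)[-100001]
  model <- azicake:::.azimuthal_model(chi, f$B0, f$A1, f$A2, 90, f$sigma)
  num_o <- sum(model - f$B0) * (360 / length(chi))
  # the chord metric makes the lobes slightly heavier than linear Gaussians,
  # so the closed form agrees with quadrature to O(sigma^2) only
  expect_equal(d$rho_oriented, num_o, tolerance = 0.01)
  expect_equal(d$rho_random, 360 * f$B0)
  # limits
  expect_equal(degree_of_orientation(list(B0 = 0, A1 = 3, A2 = 1,
                                          sigma = 10))$doo, 1)
  expect_equal(degree_of_orientation(list(B0 = 4, A1 = 0, A2 = 0,
                                          sigma = 10))$doo, 0)
  zero <- degree_of_orientation(list(B0 = 0, A1 = 0, A2 = 0, sigma = 10))
  expect_equal(zero$doo, 0)
  expect_false(isTRUE(attr(zero, "ok")))
})

test_that("fit refuses profiles with too little azimuthal support", {
  pr <- make_profile(B0 = 5, A1 = 20, A2 = 15, chi0 = 30, sigma = 12)
  pr$valid[pr$chi_centers > 150] <- FALSE
  expect_error(fit_orientation(pr), "spanning")
})

test_that("orientation maps recover a hue gradient and flag empty points", {
  radial <- seq(10.025, 13.975, by = 0.05)
  n_azi <- 36
  n_lat <- 6; n_slow <- 4
  chi0_true <- function(lat) 20 + 140 * (lat - 1) / (n_lat - 1)
  cakes <- list()
  for (slow in seq_len(n_slow)) for (lat in seq_len(n_lat)) {
    az <- function(ch, l = lat)
      2 + 30 * exp(-circular_distance(ch, chi0_true(l))^2 / (2 * 14^2)) +
      24 * exp(-circular_distance(ch, chi0_true(l) + 180)^2 / (2 * 14^2))
    I <- make_cake_matrix(radial, n_azi, peak_tt = 12, peak_sigma = 0.15,
                          area_of_chi = az, ramp = c(6, 0))
    cakes[[length(cakes) + 1L]] <- I
  }
  stack <- structure(list(
    intensity = array(unlist(cakes), dim = c(length(radial), n_azi,
                                             n_lat * n_slow)),
    radial = radial,
    azimuthal = seq(0, 360, length.out = n_azi + 1L)[-(n_azi + 1L)] +
      180 / n_azi,
    binspec = NULL, normalization = "mean"), class = "cake_stack")
  m <- orientation_map(stack, peak_window = c(11.2, 12.8),
                       bg_windows = list(c(10.2, 11.0), c(13.0, 13.8)),
                       grid_shape = c(n_lat, n_slow))
  expect_true(all(m$ok))
  for (slow in seq_len(n_slow))
    expect_true(all(diff(m$chi0[, slow]) > 0))
  expect_equal(m$chi0[, 1], vapply(seq_len(n_lat), chi0_true, 0),
               tolerance = 0.01)

  # pure-background grid: nothing significant anywhere
  flat <- stack
  flat$intensity[] <- 6
  m0 <- orientation_map(flat, peak_window = c(11.2, 12.8),
                        bg_windows = list(c(10.2, 11.0), c(13.0, 13.8)),
                        grid_shape = c(n_lat, n_slow))
  expect_false(any(m0$ok))

  # single-point grid
  m1 <- orientation_map(stack, peak_window = c(11.2, 12.8),
                        bg_windows = list(c(10.2, 11.0), c(13.0, 13.8)),
                        grid_shape = c(1, 1))
  expect_identical(dim(m1$chi0), c(1L, 1L))
  expect_true(m1$ok[1, 1])

  # HSV quick-look renders one pixel per scan point
  f <- withr::local_tempfile(fileext = ".png")
  write_orientation_png(m, f)
  img <- png::readPNG(f)
  expect_identical(dim(img)[1:2], as.integer(c(n_slow, n_lat)))
})

test_that("edge cropping removes lateral scan positions only", {
  big <- matrix(0, 110, 350)
  expect_identical(dim(crop_edges(big, 3)), c(104L, 350L))
  expect_equal(prod(dim(crop_edges(big, 3))), 36400)
  expect_identical(crop_edges(big, 0), big)
  small <- matrix(seq_len(50), 10, 5)
  expect_identical(dim(crop_edges(small, 2)), c(6L, 5L))
  expect_identical(crop_edges(small, 2), small[3:8, ])
  expect_error(crop_edges(small, 5), "margin")

  # orientation_map objects crop all layers coherently
  m <- structure(list(chi0 = big, doo = big, intensity = big,
                      ok = matrix(TRUE, 110, 350), grid_shape = c(110L, 350L)),
                 class = "orientation_map")
  mc <- crop_edges(m, 3)
  expect_identical(mc$grid_shape, c(104L, 350L))
  expect_identical(dim(mc$ok), c(104L, 350L))
})
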