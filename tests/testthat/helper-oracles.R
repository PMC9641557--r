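# Independent reference implementations used as oracles. These recompute
# the geometry and the binning transform from their definitions, without
# touching the package's vectorised slice-based code path.

# Polar coordinates of one detector point by explicit 3x3 rotation matrices
# applied to the lab-frame ray, one point at a time.
oracle_polar_one <- function(geom, r, c) {
  p <- c((r + 0.5) * geom$pixel1 - geom$poni1,
         (c + 0.5) * geom$pixel2 - geom$poni2,
         geom$distance)
  R1 <- rbind(c(1, 0, 0),
              c(0, cos(geom$rot1), -sin(geom$rot1)),
              c(0, sin(geom$rot1), cos(geom$rot1)))
  R2 <- rbind(c(cos(geom$rot2), 0, sin(geom$rot2)),
              c(0, 1, 0),
              c(-sin(geom$rot2), 0, cos(geom$rot2)))
  R3 <- rbind(c(cos(geom$rot3), -sin(geom$rot3), 0),
              c(sin(geom$rot3), cos(geom$rot3), 0),
              c(0, 0, 1))
  v <- R3 %*% R2 %*% R1 %*% p
  rho <- sqrt(v[1]^2 + v[2]^2)
  tt <- atan2(rho, v[3])
  chi <- if (rho == 0) 0 else atan2(v[1], v[2])
  c(two_theta = tt * 180 / pi, chi = (chi * 180 / pi) %% 360)
}

# Exhaustive per-sub-pixel loop: iterates every pixel and every sub-pixel
# independently and accumulates weights into a dense (bins x pixels) matrix.
oracle_build_dense <- function(geom, binspec, S, mask = NULL,
                               corrections = list()) {
  m_max <- geom$shape[1]; n_max <- geom$shape[2]
  n_bins <- binspec$n_radial * binspec$n_azimuthal
  A <- matrix(0, n_bins, m_max * n_max)
  off <- ((seq_len(S) - 1) + 0.5) / S - 0.5
  rlo <- binspec$radial_range[1]
  drad <- diff(binspec$radial_range) / binspec$n_radial
  alo <- binspec$azimuthal_range[1]
  dazi <- diff(binspec$azimuthal_range) / binspec$n_azimuthal
  for (m in seq_len(m_max) - 1L) {
    for (n in seq_len(n_max) - 1L) {
      if (!is.null(mask) && !mask[m + 1L, n + 1L]) next
      i <- m * n_max + n + 1L
      for (or in off) {
        for (oc in off) {
          pc <- oracle_polar_one(geom, m + or, n + oc)
          rv <- if (binspec$radial_unit == "two_theta_deg") pc[["two_theta"]]
          else 4 * pi * sin(pc[["two_theta"]] * pi / 360) /
            (geom$wavelength * 1e9)
          rb <- floor((rv - rlo) / drad)
          ab <- floor((pc[["chi"]] - alo) / dazi)
          if (rb < 0 || rb >= binspec$n_radial ||
              ab < 0 || ab >= binspec$n_azimuthal) next
          w <- do.call(correction_factor,
                       c(list(geom = geom,
                              coords = list(two_theta = pc[["two_theta"]],
                                            chi = pc[["chi"]])),
                         corrections)) / S^2
          j <- rb * binspec$n_azimuthal + ab + 1L
          A[j, i] <- A[j, i] + w
        }
      }
    }
  }
  A
}

# sub-pixel count per bin from the same exhaustive loop (corrections off)
oracle_subpixel_counts <- function(geom, binspec, S) {
  A <- oracle_build_dense(geom, binspec, S)
  rowSums(A) * S^2
}
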