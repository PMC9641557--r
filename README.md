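# azicake

Azimuthal integration ("caking") of 2D area-detector X-ray diffraction
frames through a precomputed sparse linear transform, plus azimuthal
texture analysis of Debye–Scherrer rings — the workflow behind scanning
XRD orientation mapping of biominerals such as bone hydroxyapatite (HAP).

## Who this is for

Synchrotron users and diffraction-data analysts who need to reduce large
stacks of detector frames to (2θ, χ) "cakes" quickly and reproducibly, and
to turn the azimuthal intensity of a chosen reflection — e.g. the HAP (002)
peak, which reports the crystallite *c*-axis — into maps of preferred
orientation, degree of orientation and crystal density over a scan grid.

## The method

**Caking as one sparse matrix product.** Each detector pixel is virtually
split into S × S sub-pixels on a regular grid. Every sub-pixel centre is
mapped to polar coordinates (2θ, χ) through the PONI calibration geometry
(detector distance, point of normal incidence, three tilts), assigned to
the polar bin containing it, and its weight 1/S² — times optional
solid-angle, polarization and Lorentz corrections evaluated *per
sub-pixel* — is accumulated into a sparse matrix **A** with one row per
(2θ, χ) bin and one column per pixel (row-major linear indices
i = m·n_max + n on both axes). Integration of a frame stack **B**
(pixels × frames) is then just

```
C = A B
```

followed by per-bin weight normalisation W_j = Σ_i w(j,i). Building **A**
is a one-off cost per setup; it is constructed in vertical detector slices
of width ⌈n_cols/S⌉ so peak memory scales as O(S) rather than O(S²), and
bins with insufficient unmasked coverage are pruned to NaN.

**How much splitting?** For azimuthally resolved work the smallest bin
(innermost radius r_min, radial width Δr, N_Ab azimuthal bins, all in pixel
units) should receive about ρ_sp sub-pixels:

```
S_min = max(10, ceil( sqrt( ρ_sp · N_Ab / (2π · r_min · Δr) ) ))
```

`recommend_splitting()` evaluates this; the floor of 10 (100 sub-pixels per
pixel) is what it takes to erase the artifact of diagonal pixels being
longer in 2θ than cardinal ones.

**Texture analysis.** For a chosen reflection, the background under the
peak is estimated per χ bin by linear interpolation in 2θ between two
flanking windows, subtracted, and the remainder integrated over 2θ. The
azimuthal profile is fitted with a two-lobe circular Gaussian

```
I(χ) = B0 + A1·exp(−d(χ, χ0)²/2σ²) + A2·exp(−d(χ, χ0+180°)²/2σ²)
d(χ, χ0) = (360/π)·sin((χ − χ0)·π/360)
```

where the chord distance d places both lobes on a circle (no edge
truncation), and the two amplitudes absorb the asymmetric Ewald-sphere
intersection. From the fit: ρ_oriented = √(2π)·σ·(A1+A2),
ρ_random = 360·B0, and the projected degree of orientation
DoO = ρ_oriented / (ρ_oriented + ρ_random) ∈ [0, 1]. Maps over a scan grid
are rendered as HSV images (hue = χ0, saturation = DoO, value = total peak
intensity).

## Worked example

Simulate one textured HAP-like frame with known ground truth, cake it, and
recover the orientation parameters:

```r
library(azicake)

geom  <- synthetic_geometry()              # 256x256 px, 75 um, 0.04 m, 17 keV
scene <- frame_scene(
  geom,
  rings = list(ring_spec(12.2, radial_sigma = 0.25, B0 = 20, A1 = 120,
                         A2 = 95, chi0 = 35, sigma_chi = 15)),
  background_level = 8, poisson = TRUE, seed = 1)
frame <- render_frame(scene)

bins  <- bin_spec(n_radial = 80, radial_range = c(10, 14), n_azimuthal = 90)
trans <- prune_bins(build_transform(geom, bins, splitting_params(S = 10)))
cake  <- integrate_chunk(trans, frame$counts)

prof <- extract_profile(cake, peak_window = c(11.6, 12.8),
                        bg_windows = list(c(10.6, 11.3), c(13.1, 13.8)))
fit  <- fit_orientation(prof)
```

This prints:

```
chi0 = 34.89 deg (true 35), sigma = 15.03 deg (true 15)
DoO = 0.527 (scene ground truth 0.529)
<sparse_transform> 80 radial x 90 azimuthal bins over 256x256 px (S = 10)
  99432 stored weights, 164 NaN bins
```

i.e. the preferred azimuth is recovered to ~0.1°, and the degree of
orientation to ~0.002 of the value implied by the generating parameters.

For file-based pipelines, `write_scan_dataset()` emits HDF5 frame stacks,
`integrate_file()` streams them in chunks (hot-pixel suppression, optional
parallel workers, chunking-invariant output) and `orientation_map()` /
`crop_edges()` / `write_orientation_png()` assemble the maps. A thin
command-line front end with `suggest-split`, `build-transform`,
`integrate`, `orient-map` and `simulate` subcommands is installed at
`system.file("cli/azicake.R", package = "azicake")`.

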