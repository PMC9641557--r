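---
title: "Sparse-matrix caking and azimuthal texture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-matrix caking and azimuthal texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azicake)
```

## The problem

A scanning X-ray diffraction experiment produces thousands to millions of
2D detector frames. Each frame must be re-gridded from pixel space to polar
(2θ, χ) space — "caked" — before any ring-resolved analysis. Because
pixels near the beam centre cover more polar area than distant ones, and
diagonal pixels are longer in 2θ than cardinal ones, naive centre-of-pixel
binning distorts azimuthally resolved intensities. azicake addresses this
with sub-pixel super-sampling folded into a precomputed sparse transform,
so that the per-frame cost collapses to one sparse matrix product, and
follows the caked data through to orientation maps of biomineral
nanocrystals.

## The transform

Pixel (m, n) (0-based, pixel-centred: it spans [m−0.5, m+0.5] ×
[n−0.5, n+0.5] in pixel units) is split into S × S sub-pixels with centre
offsets (k+0.5)/S − 0.5, k = 0..S−1, on both axes. Each sub-pixel centre is
mapped through the PONI geometry to (2θ, χ) and assigned *by its centre
point* to the half-open uniform bin containing it; its weight, 1/S² times
the sub-pixel correction factor, accumulates into the sparse matrix entry
(j, i), with i = m·n_max + n and j = j_radial·N_Ab + j_azimuthal. Sub-pixels
of masked pixels, and sub-pixels falling outside the bin ranges, contribute
nothing. The detector is processed in vertical slices of ⌈n_cols/S⌉ columns
so the working set during construction grows linearly, not quadratically,
in S.

Two bookkeeping vectors ride along: `norm` (W_j, the realised per-bin
weight) and `norm_full` (the weight the bin would receive with an empty
mask). `prune_bins()` compares the two: a bin with
W_j < min_coverage · W_full is dominated by masked area and is emptied and
recorded in `nan_bins`, so integrated output there is NaN. The default
`min_coverage = 0.5` rejects mostly-occluded bins while keeping partially
covered edge bins; the threshold is a judgement call and is configurable.
NaN bins are explicit metadata here rather than a sentinel value stored
inside the matrix; the output semantics (bin → NaN) are unchanged.

### Choosing S

`recommend_splitting()` implements
S_min = max(10, ⌈√(ρ_sp·N_Ab / (2π·r_min·Δr))⌉): the smallest bin, at the
innermost included radius, has area ≈ (2π·r_min/N_Ab)·Δr in pixel units,
and requiring ρ_sp sub-pixels of area 1/S² inside it gives the root term.
This closed form is a *reconstruction* from the area argument (the
defining relation is stated in terms of its four factors: N_Ab, ρ_sp,
r_min, Δr); it is validated in the test suite by monotonicity in all four
arguments and by exhaustively counting sub-pixels in the innermost radial
ring at S = S_min. The floor of 10 for azimuthally resolved work (100
sub-pixels per pixel) is the level at which the diagonal-pixel artifact on
an isotropic ring disappears, which the suite checks as a drop in the
azimuthal coefficient of variation between S = 1 and S = 10. When the bin
ranges start at the beam centre the area argument has no finite answer and
the under-splitting warning is suppressed.

### Geometry and corrections

The PONI convention is used throughout: `distance` is sample-to-PONI along
the detector normal, and rotations rot1–rot3 (about the lab slow, fast and
beam axes, applied in that order) tilt the detector plane. χ = 0 lies along
the detector +column axis and increases towards the +row axis, reported in
degrees in [0, 360); at the beam centre χ is undefined and reported as 0.
No convention is canonical for χ — but orientation hues depend on it, so it
is fixed and documented here, and absolute hue values are only comparable
between datasets processed with the same convention.

Corrections are evaluated at sub-pixel, not pixel, resolution:

* **Solid angle** — cos³α, α the incidence angle of the scattered ray on
  the detector plane (for an orthogonal detector this is cos³ 2θ,
  normalised to 1 in the forward beam).
* **Polarization** — Kahn-type factor for a horizontally polarized beam,
  with fraction p (default 0.99 when enabled, synchrotron-typical).
* **Lorentz** — the 1/sin 2θ texture-analysis shape, normalised to 1 at a
  small-angle guard floor (default 1° 2θ) so it stays finite and continuous
  through the forward beam. It is **off by default**: it belongs to
  specific texture workflows and there is no universal convention for
  whether reduction pipelines apply it.

All three are individually switchable and validated only by limit and
quadrature tests, since the choice of correction formulas is a convention,
not something with a single printed reference value.

## Integration

`integrate_chunk()` flattens d frames to B (pixels × d) by the same
row-major rule, computes C = A·B, and divides by W_j ("mean"
normalisation, the default) or not ("sum"). Mean normalisation makes bin
values intensity-like and invariant to how much detector area feeds a bin,
which is the convention of mainstream integrators; sum mode is provided
because which one a given legacy pipeline used is not always knowable.
Pixels flagged NA by `remove_hot_pixels()` (default rule: exceeding 8× the
frame's 99.9th percentile — conservative, configurable, and meaningful
only on frames large enough that the percentile sits in the background)
are zeroed *and their weight subtracted from W_j for that frame only*, so
a transient zinger cannot bias the mean.

`integrate_file()` streams an HDF5 stack in chunks of `chunk_d` frames
(optionally across forked workers) and reassembles in frame order; outputs
are bit-identical across chunk sizes and worker counts because no
reduction ever crosses a chunk boundary. Per-stage wall-clock timing
(load, preprocess, integrate, save, overhead) is returned for profiling.
`collapse_to_1d()` reduces a cake to 1D patterns by the W_j-weighted mean
over non-NaN χ bins, which agrees with a dedicated N_Ab = 1 transform up
to the residual S-refinement error of the caked route.

## Orientation analysis

For one reflection (for bone, HAP (002), whose azimuthal intensity tracks
the crystallite c-axis in projection):

1. **Profile extraction.** Per χ bin, the background under the peak window
   is a straight line in 2θ through the mean intensities of two flanking
   windows; the background-subtracted peak is integrated over 2θ (× bin
   width, so the profile is an area). Linear interpolation between flanks
   was chosen over a constant offset because diffuse scattering slopes
   across typical peak windows; it costs nothing and cancels exactly for
   backgrounds linear in 2θ. Any NaN inside the peak window invalidates
   that χ bin.
2. **Two-lobe fit.** I(χ) = B0 + A1·G(χ−χ0) + A2·G(χ−χ0−180°) with
   Gaussian lobes in the chord distance d(χ,χ0) = (360/π)·sin((χ−χ0)π/360).
   The chord form is smooth and 360°-periodic, reduces to |χ−χ0| for small
   separations, and avoids truncation artifacts at the profile edges; like
   the S_min formula it is a reconstruction justified by its limiting
   behaviour, and the package's accuracy claims rest on parameter-recovery
   tests, not on equation identity with any particular reference. Fitting
   is bounded Levenberg–Marquardt (B0, A1, A2 ≥ 0, σ ∈ [0.01°, 120°]) with
   a χ0 multi-start every 15° to escape the 180° ambiguity; χ0 is reported
   mod 180° with the lobe amplitudes swapped on folding.
3. **Degree of orientation.** ρ_oriented = √(2π)·σ·(A1+A2) (lobe area over
   χ), ρ_random = 360·B0 (isotropic area over the circle),
   DoO = ρ_oriented/(ρ_oriented+ρ_random). Because the lobes live in the
   chord metric, the √(2π)σ area is exact only to O(σ²); quadrature agrees
   to ~0.5% at σ = 10°, well below the noise level of per-point fits. A fit
   is flagged not-ok when the optimiser fails or the lobe area does not
   exceed `significance` (default 5) × residual SD × √n_bins — such points
   render black in the HSV map rather than aborting a whole scan.

`orientation_map()` applies the pipeline per scan point. Grids store the
lateral (fast) scan axis as the first array dimension, and `crop_edges()`
removes a margin of lateral positions from both ends — continuous-scan
turnarounds corrupt the outermost columns — so a 110 × 350 grid cropped by
3 keeps 104 × 350 = 36400 points.

## The synthetic generator

`frame_scene()`/`render_frame()` emulate the target experiment: rings with
Gaussian radial profiles whose azimuthal modulation uses the *same*
two-lobe model and chord metric as the fit (closed-loop by construction; a
von Mises variant exists precisely to break that loop and probe model
misspecification), flat background, optional Poisson noise under a fixed
seed, hot pixels written last, masked pixels reading zero. Ground truth —
ring positions, azimuthal parameters, analytic DoO — travels with every
frame and into the JSON sidecar of `write_scan_dataset()`, which splits
scan frames across HDF5 files (last file ragged) in the dialect
`integrate_file()` reads.

The default toy geometry is 256 × 256 pixels of 75 µm at 0.04 m and
17 keV. The short distance is deliberate: it places the HAP (002) ring
(d ≈ 3.44 Å, 2θ ≈ 12.2° at 17 keV) at ≈115 px radius, on-detector for a
256-pixel toy chip, with the ~15° multiplet reaching the corners. A
realistic beamline distance with a 4M-pixel detector would scale both the
chip and the radii up without changing any algorithmic behaviour.

What the generator does **not** emulate: charge sharing, flat-field error,
detector point-spread, compression artifacts, or fluorescence signal.
Passing the recovery suites therefore demonstrates correctness of the
transform and fitting machinery under known ground truth — not robustness
to every systematic a real detector adds.

## Numerical choices and problem sizes

* Sub-pixel assignment is by centre point; no sub-pixel area splitting.
  Bins are half-open [lo, hi), so a value on an edge belongs to the upper
  bin and no double counting can occur.
* Weights accumulate as doubles; a pixel fully inside the ranges has
  column sum exactly 1 (to the last bit) with corrections off, which the
  suite asserts at 1e−12.
* The transform archive stores CSC `indices`/`indptr`/`weights` plus the
  normalisation vectors, NaN bins and a JSON metadata block (geometry and
  mask fingerprints, S, bin spec); loading validates structural
  consistency and `integrate_chunk()` rejects frames whose shape
  contradicts the fingerprint.
* Test and validation sizes are kept desk-scale on purpose: oracle
  equivalence on randomized detectors up to 64 × 64 at S ≤ 6 against an
  exhaustive per-sub-pixel loop; constant-frame preservation at S ∈
  {1, 5, 20} on 40 × 40; ring recovery on 96 × 96 at S ∈ {1, 10}; 200
  noisy profiles for orientation recovery; a 100-frame file for
  chunk/worker invariance. These sizes exercise every code path (slicing,
  masking, pruning, ragged chunks, forked workers) while a full run of the
  suite stays in the tens of seconds.

## Known limitations

* Geometry calibration itself (refining the PONI from calibrant rings) is
  out of scope; import a PONI from a dedicated calibration tool.
* q-space output is a monotone relabelling of 2θ bin edges, not a
  resampling.
* The orientation maps are projections: crystallites with their scattering
  vector along the beam are invisible, and DoO is a projected quantity.
* Absolute χ0 hues depend on the documented χ convention; compare maps
  only within one convention.
* No GPU path and no live-streaming input; files are the unit of work.
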