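Package: azicake
Title: Sparse-Matrix Azimuthal Integration and Texture Mapping of 2D Diffraction Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Azimuthal integration ("caking") of 2D area-detector diffraction
    frames through a precomputed sparse linear transform from detector pixel
    space to (2-theta, chi) polar bins, built by S-by-S sub-pixel
    super-sampling in memory-bounded detector slices. Includes PONI-dialect
    geometry handling with sub-pixel-level solid-angle, polarization and
    Lorentz corrections, chunked streaming integration of HDF5 frame stacks
    with hot-pixel suppression, azimuthal texture analysis of Debye-Scherrer
    rings (two-lobe circular Gaussian fits, degree-of-orientation and
    crystal-density maps over scan grids, as used for bone hydroxyapatite
    (002) orientation mapping), and a synthetic frame generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    parallel,
    png,
    rhdf5,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
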