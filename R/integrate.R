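# Applying the sparse transform to frame stacks: hot-pixel suppression,
# the C = A B product, chunked file streaming and 1D collapse.

#' Suppress hot pixels in a frame chunk
#'
#' Flags spurious high-intensity pixels (zingers, cosmic rays, readout
#' artifacts) not caught by the static mask and excludes them from this
#' chunk only — the transform is untouched. Flagged pixels are set to `NA`;
#' [integrate_chunk()] removes their weight from the per-bin normalisation
#' for the affected frames.
#'
#' The default robust rule flags pixels exceeding `multiplier` times the
#' frame's `prob` quantile; an absolute `cutoff` can be used instead or in
#' addition.
#'
#' @param frames Integer/numeric array `(n_rows, n_cols, d)` or a single
#'   matrix.
#' @param rule `"quantile"` (default) or `"absolute"`.
#' @param multiplier,prob Parameters of the quantile rule: flag values
#'   `> multiplier * quantile(frame, prob)`. Defaults 8 and 0.999.
#' @param cutoff Absolute cutoff for `rule = "absolute"`.
#' @param verbose Emit a message with the number of removals.
#' @return The frames with flagged pixels set to `NA`; the removal count is
#'   attached as attribute `"n_removed"`.
#' @export
remove_hot_pixels <- function(frames, rule = c("quantile", "absolute"),
                              multiplier = 8, prob = 0.999, cutoff = Inf,
                              verbose = FALSE) {
  rule <- match.arg(rule)
  x <- .as_frame_array(frames)
  n_removed <- 0L
  for (k in seq_len(dim(x)[3])) {
    fr <- x[, , k]
    thr <- if (rule == "quantile")
      multiplier * stats::quantile(fr, prob, na.rm = TRUE, names = FALSE)
    else cutoff
    hot <- !is.na(fr) & fr > thr
    if (any(hot)) {
      fr[hot] <- NA
      x[, , k] <- fr
      n_removed <- n_removed + sum(hot)
    }
  }
  if (verbose) message("remove_hot_pixels: flagged ", n_removed, " pixel(s)")
  out <- if (is.matrix(frames)) x[, , 1] else x
  attr(out, "n_removed") <- n_removed
  out
}

.as_frame_array <- function(frames) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3L)
    stop("frames must be a (n_rows, n_cols, d) array or a matrix")
  frames
}

#' Integrate a chunk of frames through a sparse transform
#'
#' Reshapes the chunk to a `(n_pixels, d)` matrix `B` by the same row-major
#' linearisation the transform was built with and computes the cake
#' `C = A B`. Under `"mean"` normalisation each bin is divided by its total
#' weight `W_j` (adjusted per frame for pixels excluded as `NA`), making bin
#' values intensity-like and mask-invariant; `"sum"` returns raw weighted
#' sums. Bins in `nan_bins`, and bins with no remaining weight, are NaN.
#'
#' @param t A `sparse_transform`.
#' @param frames `(n_rows, n_cols, d)` array or a matrix; `NA` marks pixels
#'   excluded for this chunk (see [remove_hot_pixels()]).
#' @param normalization `"mean"` (default) or `"sum"`.
#' @return A `"cake_stack"`: list with `intensity`
#'   `(n_radial, n_azimuthal, d)`, the axes `radial` and `azimuthal` (bin
#'   centres), the `binspec` and the normalisation mode.
#' @export
integrate_chunk <- function(t, frames, normalization = c("mean", "sum")) {
  stopifnot(inherits(t, "sparse_transform"))
  normalization <- match.arg(normalization)
  x <- .as_frame_array(frames)
  shp <- t$meta$shape
  if (dim(x)[1] != shp[1] || dim(x)[2] != shp[2])
    stop("frame shape ", dim(x)[1], "x", dim(x)[2],
         " does not match transform fingerprint (", shp[1], "x", shp[2], ")")
  d <- dim(x)[3]
  binspec <- t$meta$binspec
  # row-major flatten: B[i + 1, k] = frame[m + 1, n + 1] with i = m*n_max + n
  B <- matrix(aperm(x, c(2, 1, 3)), nrow = prod(shp), ncol = d)
  nas <- is.na(B)
  any_na <- any(nas)
  if (any_na) B[nas] <- 0
  C <- as.matrix(t$A %*% B)
  if (normalization == "mean") {
    W <- matrix(t$norm, nrow = length(t$norm), ncol = d)
    if (any_na) W <- W - as.matrix(t$A %*% (nas * 1))
    C <- C / ifelse(W > 0, W, NA_real_)
  }
  if (length(t$nan_bins)) C[t$nan_bins, ] <- NaN
  C[is.na(C)] <- NaN
  # bin j = rbin * n_azimuthal + abin (row-major) -> (radial, azimuthal, d)
  intensity <- aperm(array(C, dim = c(binspec$n_azimuthal, binspec$n_radial, d)),
                     c(2, 1, 3))
  structure(list(intensity = intensity,
                 radial = radial_centers(binspec),
                 azimuthal = azimuthal_centers(binspec),
                 binspec = binspec,
                 normalization = normalization),
            class = "cake_stack")
}

#' @export
print.cake_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<cake_stack> ", d[1], " radial x ", d[2], " azimuthal x ", d[3],
      " frame(s), ", x$normalization, "-normalized\n", sep = "")
  invisible(x)
}

#' Stream an HDF5 frame-stack file through the transform
#'
#' Loads the stack in chunks of `chunk_d` frames, optionally suppresses hot
#' pixels per chunk, integrates each chunk with [integrate_chunk()] and
#' writes a single output HDF5 file containing the full cake stack in input
#' frame order, the bin-centre axes, the 1D collapsed patterns and
#' provenance attributes. Results are independent of `chunk_d` and
#' `workers`.
#'
#' @param t A `sparse_transform`.
#' @param input_path HDF5 file with an integer frame dataset.
#' @param output_path Output HDF5 path (overwritten).
#' @param chunk_d Frames per chunk (default 10; < 20 is typical).
#' @param workers Number of parallel workers over chunks (forked; 1 =
#'   sequential). Output is reassembled in frame order either way.
#' @param normalization Passed to [integrate_chunk()].
#' @param dataset Path of the frame dataset inside the file.
#' @param hot_pixels Logical; apply [remove_hot_pixels()] per chunk.
#' @param ... Extra arguments for [remove_hot_pixels()].
#' @return Invisibly, a summary list: `n_frames`, `chunks`, per-stage
#'   `timing` in seconds (load, preprocess, integrate, save, overhead) and
#'   `hot_pixels_removed`.
#' @export
integrate_file <- function(t, input_path, output_path, chunk_d = 10L,
                           workers = 1L, normalization = "mean",
                           dataset = "entry/data/data", hot_pixels = TRUE,
                           ...) {
  stopifnot(inherits(t, "sparse_transform"))
  if (!file.exists(input_path)) stop("input file not found: ", input_path)
  t_all <- proc.time()[["elapsed"]]
  dims <- .h5_dataset_dims(input_path, dataset)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  n_frames <- dims[3]
  starts <- seq(1L, n_frames, by = as.integer(chunk_d))
  chunks <- lapply(starts, function(s) s:min(s + chunk_d - 1L, n_frames))

  timing <- c(load = 0, preprocess = 0, integrate = 0, save = 0, overhead = 0)
  run_chunk <- function(idx) {
    t0 <- proc.time()[["elapsed"]]
    x <- tryCatch(
      rhdf5::h5read(input_path, dataset, index = list(NULL, NULL, idx)),
      error = function(e) stop("failed to read frames ", min(idx), "-",
                               max(idx), " from ", input_path, ": ",
                               conditionMessage(e)))
    if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
    storage.mode(x) <- "double"
    t1 <- proc.time()[["elapsed"]]
    n_hot <- 0L
    if (hot_pixels) {
      x <- remove_hot_pixels(x, ...)
      n_hot <- attr(x, "n_removed")
    }
    t2 <- proc.time()[["elapsed"]]
    cake <- integrate_chunk(t, x, normalization = normalization)
    t3 <- proc.time()[["elapsed"]]
    list(intensity = cake$intensity, n_hot = n_hot,
         times = c(load = t1 - t0, preprocess = t2 - t1, integrate = t3 - t2))
  }
  results <- if (workers > 1L)
    parallel::mclapply(chunks, run_chunk, mc.cores = workers,
                       mc.preschedule = FALSE)
  else lapply(chunks, run_chunk)
  errs <- vapply(results, inherits, logical(1), "try-error")
  if (any(errs)) stop(results[[which(errs)[1]]])

  binspec <- t$meta$binspec
  intensity <- array(NA_real_,
                     dim = c(binspec$n_radial, binspec$n_azimuthal, n_frames))
  for (k in seq_along(chunks))
    intensity[, , chunks[[k]]] <- results[[k]]$intensity
  for (nm in c("load", "preprocess", "integrate"))
    timing[nm] <- sum(vapply(results, function(r) r$times[[nm]], 0))

  t_save <- proc.time()[["elapsed"]]
  cake <- structure(list(intensity = intensity,
                         radial = radial_centers(binspec),
                         azimuthal = azimuthal_centers(binspec),
                         binspec = binspec, normalization = normalization),
                    class = "cake_stack")
  pattern <- collapse_to_1d(cake, t)
  .write_cake_h5(output_path, cake, pattern, t, normalization)
  timing["save"] <- proc.time()[["elapsed"]] - t_save
  timing["overhead"] <- max(0, proc.time()[["elapsed"]] - t_all - sum(timing))
  invisible(list(n_frames = n_frames, chunks = lengths(chunks),
                 timing = timing,
                 hot_pixels_removed = sum(vapply(results, `[[`, 0L, "n_hot"))))
}

.h5_dataset_dims <- function(path, dataset) {
  info <- rhdf5::h5ls(path)
  full <- paste(sub("/$", "", info$group), info$name, sep = "/")
  row <- info[full == paste0("/", sub("^/", "", dataset)), , drop = FALSE]
  if (nrow(row) == 0L) stop("dataset `", dataset, "` not found in ", path)
  as.integer(strsplit(row$dim[1], " x ", fixed = TRUE)[[1]])
}

.write_cake_h5 <- function(path, cake, pattern, t, normalization) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cake$intensity, path, "cake")
  rhdf5::h5write(cake$radial, path, "radial_axis")
  rhdf5::h5write(cake$azimuthal, path, "azimuthal_axis")
  rhdf5::h5write(pattern, path, "pattern_1d")
  rhdf5::h5write(as.character(.meta_to_json(t$meta)), path, "transform_meta")
  rhdf5::h5write(normalization, path, "normalization")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a cake stack written by [integrate_file()]
#' @param path Cake HDF5 file.
#' @return A `"cake_stack"` (with the 1D patterns attached as `pattern_1d`).
#' @export
read_cake <- function(path) {
  meta <- .meta_from_json(as.character(rhdf5::h5read(path, "transform_meta")))
  out <- structure(list(intensity = rhdf5::h5read(path, "cake"),
                        radial = as.numeric(rhdf5::h5read(path, "radial_axis")),
                        azimuthal = as.numeric(rhdf5::h5read(path, "azimuthal_axis")),
                        binspec = meta$binspec,
                        normalization = as.character(rhdf5::h5read(path, "normalization"))),
                   class = "cake_stack")
  out$pattern_1d <- rhdf5::h5read(path, "pattern_1d")
  rhdf5::h5closeAll()
  out
}

#' Collapse a cake stack to 1D diffraction patterns
#'
#' Weighted mean over the non-NaN azimuthal bins of each radial bin, using
#' the transform's per-bin weights `W_j`, so the collapse reproduces what a
#' full 1D azimuthal integration of the same frame would give. Radial rows
#' whose azimuthal bins are all NaN collapse to NaN.
#'
#' @param cake A mean-normalized `cake_stack`.
#' @param t The `sparse_transform` that produced it (source of `W_j`).
#' @return Matrix `(n_radial, d)` of 1D patterns.
#' @export
collapse_to_1d <- function(cake, t) {
  stopifnot(inherits(cake, "cake_stack"), inherits(t, "sparse_transform"))
  b <- cake$binspec
  W <- matrix(t$norm, nrow = b$n_radial, ncol = b$n_azimuthal, byrow = TRUE)
  d <- dim(cake$intensity)[3]
  out <- matrix(NA_real_, b$n_radial, d)
  for (k in seq_len(d)) {
    I <- cake$intensity[, , k]
    ok <- is.finite(I) & W > 0
    num <- rowSums(ifelse(ok, W * I, 0))
    den <- rowSums(ifelse(ok, W, 0))
    out[, k] <- ifelse(den > 0, num / den, NaN)
  }
  out
}
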