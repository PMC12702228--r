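#' Construct a hyperspectral Raman cube
#'
#' The universal data container of the package: an `H x W x B` intensity
#' volume (height, width, spectral bands) with a strictly increasing
#' wavenumber axis in reciprocal centimetres. The spectral axis is always
#' the third array dimension.
#'
#' @param data Numeric 3-d array, dimensions `c(H, W, B)`. All values must
#'   be finite.
#' @param wavenumbers Numeric vector of length `B`, strictly increasing
#'   Raman shifts in cm^-1.
#' @param pixel_size Optional spatial resolution in micrometres (> 0).
#' @param integration_time Optional per-pixel acquisition time in seconds.
#' @param provenance Free-text origin tag, e.g. `"phantom"`.
#'
#' @return An object of class `hyper_cube`: a list with elements `data`,
#'   `wavenumbers`, `pixel_size`, `integration_time`, `provenance`.
#' @export
#' @examples
#' cube <- hyper_cube(array(runif(4 * 4 * 8), c(4, 4, 8)), seq(500, 1800, length.out = 8))
#' dim(cube$data)
hyper_cube <- function(data, wavenumbers, pixel_size = NULL,
                       integration_time = NULL, provenance = "unknown") {
  cube <- structure(
    list(data = data, wavenumbers = as.numeric(wavenumbers),
         pixel_size = pixel_size, integration_time = integration_time,
         provenance = as.character(provenance)[1]),
    class = "hyper_cube")
  validate_cube(cube)
  cube
}

#' Validate a hyperspectral cube
#'
#' Checks the container invariants: 3 axes, axis length matching the data,
#' strictly increasing wavenumbers, finite values, positive dimensions.
#'
#' @param cube A `hyper_cube`.
#' @return The cube, invisibly, if valid; otherwise an error is raised.
#' @export
validate_cube <- function(cube) {
  if (!is.list(cube) || is.null(cube$data) || is.null(cube$wavenumbers))
    stop("cube must carry `data` and `wavenumbers`", call. = FALSE)
  d <- dim(cube$data)
  if (is.null(d) || length(d) != 3L)
    stop("cube data must have exactly 3 axes (H, W, B)", call. = FALSE)
  if (any(d < 1L))
    stop("all cube dimensions must be >= 1", call. = FALSE)
  if (length(cube$wavenumbers) != d[3L])
    stop(sprintf("wavenumber axis length (%d) does not match spectral axis (%d)",
                 length(cube$wavenumbers), d[3L]), call. = FALSE)
  if (d[3L] > 1L && any(diff(cube$wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (!all(is.finite(cube$data)))
    stop("cube data contains NaN or infinite values", call. = FALSE)
  if (!is.null(cube$pixel_size) && cube$pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  invisible(cube)
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral Raman cube: %d x %d px, %d bands (%.1f-%.1f cm^-1)\n",
              d[1], d[2], d[3], x$wavenumbers[1], x$wavenumbers[d[3]]))
  cat(sprintf("  intensity range [%.4g, %.4g], provenance: %s\n",
              min(x$data), max(x$data), x$provenance))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um\n", x$pixel_size))
  if (!is.null(x$integration_time))
    cat(sprintf("  integration time: %g s/pixel\n", x$integration_time))
  invisible(x)
}

#' Read a hyperspectral cube from its HDF5 container
#'
#' Container layout: dataset `/cube` (H x W x B, float32), dataset
#' `/wavenumber_cm1` (length B, float64), root attributes
#' `pixel_size_um`, `integration_time_s` (optional), `provenance`,
#' `format_version`.
#'
#' @param path Path to an HDF5 file following the container layout.
#' @return A validated [hyper_cube].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE),
                       error = function(e) stop(sprintf(
                         "not a readable HDF5 container: %s", path), call. = FALSE))
  names_present <- contents$name
  if (!"cube" %in% names_present)
    stop("container format error: missing dataset /cube", call. = FALSE)
  if (!"wavenumber_cm1" %in% names_present)
    stop("container format error: missing dataset /wavenumber_cm1", call. = FALSE)
  data <- rhdf5::h5read(path, "cube")
  wn <- as.numeric(rhdf5::h5read(path, "wavenumber_cm1"))
  attrs <- rhdf5::h5readAttributes(path, "/")
  read_attr <- function(name, default = NULL) {
    v <- attrs[[name]]
    if (is.null(v)) default else as.vector(v)
  }
  d <- dim(data)
  if (length(d) != 3L)
    stop("container shape error: /cube does not have 3 axes", call. = FALSE)
  if (length(wn) != d[3L])
    stop(sprintf("container shape error: wavenumber axis length %d != %d bands",
                 length(wn), d[3L]), call. = FALSE)
  hyper_cube(
    data = data, wavenumbers = wn,
    pixel_size = read_attr("pixel_size_um"),
    integration_time = read_attr("integration_time_s"),
    provenance = {
      p <- read_attr("provenance", "unknown")
      as.character(p)[1]
    })
}

#' Write a hyperspectral cube to an HDF5 container
#'
#' Intensities are stored as 32-bit floats, the wavenumber axis as 64-bit
#' floats; [read_cube] recovers them bit-exactly at that stored precision.
#'
#' @param cube A valid [hyper_cube].
#' @param path Destination file path.
#' @param overwrite Overwrite an existing file? Default `FALSE`: writing to
#'   an existing path without this flag is an error.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, overwrite = FALSE) {
  validate_cube(cube)
  if (file.exists(path)) {
    if (!overwrite)
      stop(sprintf("refusing to overwrite existing file %s (use overwrite = TRUE)",
                   path), call. = FALSE)
    unlink(path)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop(sprintf("cannot create file at %s", path), call. = FALSE)
  # round-trip through float32 so file and memory agree bit-exactly
  rhdf5::h5createDataset(path, "cube", dims = dim(cube$data),
                         storage.mode = "double", H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(cube$data, path, "cube")
  rhdf5::h5write(as.numeric(cube$wavenumbers), path, "wavenumber_cm1")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (!is.null(cube$pixel_size))
    rhdf5::h5writeAttribute(as.numeric(cube$pixel_size), fid, "pixel_size_um")
  if (!is.null(cube$integration_time))
    rhdf5::h5writeAttribute(as.numeric(cube$integration_time), fid, "integration_time_s")
  rhdf5::h5writeAttribute(cube$provenance, fid, "provenance")
  rhdf5::h5writeAttribute("1.0", fid, "format_version")
  invisible(path)
}

#' Export one pixel spectrum as CSV
#'
#' Writes the spectrum at `(row, col)` as a two-column CSV
#' (`wavenumber_cm1`, `intensity`) for quick inspection.
#'
#' @param cube A [hyper_cube].
#' @param row,col Pixel coordinates (1-based).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_spectrum <- function(cube, row, col, path) {
  validate_cube(cube)
  d <- dim(cube$data)
  if (row < 1 || row > d[1] || col < 1 || col > d[2])
    stop("pixel coordinates outside the image", call. = FALSE)
  utils::write.csv(
    data.frame(wavenumber_cm1 = cube$wavenumbers,
               intensity = cube$data[row, col, ]),
    path, row.names = FALSE)
  invisible(path)
}

#' Snap doubles to the container's stored precision
#'
#' The HDF5 container stores intensities as 32-bit floats. This helper
#' rounds a numeric vector or array to the nearest float32-representable
#' value, so that a value written with [write_cube] and read back with
#' [read_cube] compares bit-exactly.
#'
#' @param x Numeric vector or array.
#' @return `x` with every element on the float32 grid (still stored as
#'   doubles in R).
#' @export
as_float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Min-max normalization of a cube
#'
#' Rescales the cube to `[0, 1]` with one global (min, max) pair taken over
#' all `H * W * B` intensities, `x' = (x - min) / (max - min)`. A constant
#' (degenerate) cube maps to all zeros and is flagged rather than raising
#' an error, so batch pipelines keep running on empty background tiles.
#'
#' @param cube A valid [hyper_cube].
#' @return A list with `cube` (the normalized [hyper_cube]) and `scale`, a
#'   `scale_record` with fields `x_min`, `x_max`, `degenerate`.
#' @seealso [denormalize_cube]
#' @export
min_max_normalize <- function(cube) {
  validate_cube(cube)
  x_min <- min(cube$data)
  x_max <- max(cube$data)
  degenerate <- x_max == x_min
  out <- cube
  out$data <- if (degenerate) array(0, dim(cube$data))
              else (cube$data - x_min) / (x_max - x_min)
  list(cube = out,
       scale = structure(list(x_min = x_min, x_max = x_max,
                              degenerate = degenerate),
                         class = "scale_record"))
}

#' Invert a min-max normalization
#'
#' @param cube A normalized [hyper_cube].
#' @param scale The `scale_record` returned by [min_max_normalize].
#' @return The cube on the original intensity scale.
#' @export
denormalize_cube <- function(cube, scale) {
  out <- cube
  out$data <- if (isTRUE(scale$degenerate)) {
    array(scale$x_min, dim(cube$data))
  } else {
    cube$data * (scale$x_max - scale$x_min) + scale$x_min
  }
  out
}

#' Apply an existing scale record to another cube
#'
#' Used to bring the noisy member of a training pair onto the same `[0, 1]`
#' scale as its clean reference.
#'
#' @param cube A [hyper_cube].
#' @param scale A `scale_record`.
#' @return The rescaled cube (not clipped; values may fall outside `[0, 1]`).
#' @export
apply_scale <- function(cube, scale) {
  out <- cube
  out$data <- if (isTRUE(scale$degenerate)) array(0, dim(cube$data))
              else (cube$data - scale$x_min) / (scale$x_max - scale$x_min)
  out
}
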