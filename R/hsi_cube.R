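#' Hyperspectral image cube
#'
#' An `hsi_cube` holds a `W x H x S` array of absorbance values (arbitrary
#' units) together with its spectral axis in wavenumbers (cm^-1).  The
#' first array dimension indexes samples (columns within a scan line), the
#' second lines (spatial rows), the third spectral bands.
#'
#' @param data numeric 3-D array, `W x H x S`, all values finite.
#' @param wavenumbers length-`S` strictly monotone numeric vector (cm^-1),
#'   ascending or descending.  Defaults to band indices `1:S`.
#' @param interleave_origin layout of the source file (`"BSQ"`, `"BIL"` or
#'   `"BIP"`); purely informational.
#' @param metadata free-form named list (description, pixel size, ...).
#' @return an object of class `hsi_cube`.
#' @seealso [cube_to_matrix()], [read_envi()], [simulate_hsi()]
#' @export
hsi_cube <- function(data, wavenumbers = NULL, interleave_origin = "BSQ",
                     metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (W x H x S)")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L || d[3] < 2L)
    stop("cube must have W >= 1, H >= 1 and S >= 2 bands")
  if (!all(is.finite(data)))
    stop("cube contains non-finite absorbance values")
  if (is.null(wavenumbers)) wavenumbers <- as.numeric(seq_len(d[3]))
  if (length(wavenumbers) != d[3])
    stop("`wavenumbers` must have length S = ", d[3])
  dv <- diff(wavenumbers)
  if (!(all(dv > 0) || all(dv < 0)))
    stop("`wavenumbers` must be strictly monotone")
  interleave_origin <- match.arg(toupper(interleave_origin),
                                 c("BSQ", "BIL", "BIP"))
  structure(
    list(data = data, wavenumbers = as.numeric(wavenumbers),
         interleave_origin = interleave_origin, metadata = metadata),
    class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f to %.1f cm-1), origin %s\n",
              d[1], d[2], d[3], x$wavenumbers[1], x$wavenumbers[d[3]],
              x$interleave_origin))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Pixel-by-band matrix view of a cube
#'
#' A `pixel_matrix` is the `N x S` (`N = W * H`) reshaped view on which
#' all covariance algebra operates: row `j` is the spectrum of pixel `j`,
#' column `i` is the flattened image of band `i`.
#'
#' @param Y numeric `N x S` matrix.
#' @param width,height spatial dimensions with `width * height == nrow(Y)`.
#' @param wavenumbers length-`S` spectral axis.
#' @return an object of class `pixel_matrix`.
#' @export
pixel_matrix <- function(Y, width, height, wavenumbers = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) != width * height)
    stop("nrow(Y) must equal width * height")
  if (is.null(wavenumbers)) wavenumbers <- as.numeric(seq_len(ncol(Y)))
  if (length(wavenumbers) != ncol(Y))
    stop("`wavenumbers` must have length S = ", ncol(Y))
  structure(list(Y = Y, width = as.integer(width), height = as.integer(height),
                 wavenumbers = as.numeric(wavenumbers)),
            class = "pixel_matrix")
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf("<pixel_matrix> %d pixels (%d x %d) x %d bands\n",
              nrow(x$Y), x$width, x$height, ncol(x$Y)))
  invisible(x)
}

#' @export
dim.pixel_matrix <- function(x) dim(x$Y)

#' Reshape a cube into its pixel matrix
#'
#' Pixel ordering is row-major over spatial lines: pixel index
#' `j = (line - 1) * W + sample`, i.e. samples vary fastest within a line.
#' This matches R's column-major flattening of the `W x H x S` array, so
#' the round trip through [matrix_to_cube()] is bit-exact.
#'
#' @param cube an [hsi_cube()].
#' @return a [pixel_matrix()].
#' @export
cube_to_matrix <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  pixel_matrix(matrix(cube$data, nrow = d[1] * d[2], ncol = d[3]),
               width = d[1], height = d[2], wavenumbers = cube$wavenumbers)
}

#' Reshape a pixel matrix back into a cube
#'
#' Exact inverse of [cube_to_matrix()].
#'
#' @param pm a [pixel_matrix()].
#' @param interleave_origin,metadata passed to [hsi_cube()].
#' @return an [hsi_cube()].
#' @export
matrix_to_cube <- function(pm, interleave_origin = "BSQ", metadata = list()) {
  stopifnot(inherits(pm, "pixel_matrix"))
  hsi_cube(array(pm$Y, dim = c(pm$width, pm$height, ncol(pm$Y))),
           wavenumbers = pm$wavenumbers,
           interleave_origin = interleave_origin, metadata = metadata)
}

#' Extract one band as a spatial image
#'
#' @param x a [pixel_matrix()] or [hsi_cube()].
#' @param band band index in `1:S`.
#' @return a `W x H` numeric matrix.
#' @export
band_image <- function(x, band) {
  if (inherits(x, "hsi_cube")) return(x$data[, , band])
  stopifnot(inherits(x, "pixel_matrix"))
  matrix(x$Y[, band], nrow = x$width, ncol = x$height)
}
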