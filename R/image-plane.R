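#' Construct an image plane
#'
#' An image plane is a numeric matrix of fluorescence intensities (arbitrary
#' units, a.u.) carrying the physical pixel size, the role of the channel in
#' the assay, and an optional acquisition time. Rows index the vertical image
#' axis, columns the horizontal one; pixel `(i, j)` is centred at the integer
#' coordinate `(i, j)` (1-based).
#'
#' @param intensities Numeric matrix of non-negative, finite intensities,
#'   at least 16 x 16.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @param channel Channel role: `"marker"` (granule-defining, e.g.
#'   FUS-mCherry or G3BP), `"probe"` (e.g. SOD1-GFP), or `"stain"`.
#' @param time_s Optional acquisition time in seconds.
#' @return An `image_plane` object (a matrix with metadata attributes).
#' @examples
#' img <- image_plane(matrix(100, 32, 32), pixel_size_um = 0.135)
#' pixel_size(img)
#' @export
image_plane <- function(intensities, pixel_size_um = 0.135,
                        channel = c("marker", "probe", "stain"),
                        time_s = NULL) {
  channel <- match.arg(channel)
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix.")
  }
  if (any(!is.finite(intensities))) {
    abort("`intensities` must be finite everywhere (no NA/NaN/Inf pixels).")
  }
  if (any(intensities < 0)) {
    abort("`intensities` must be non-negative.")
  }
  if (nrow(intensities) < 16L || ncol(intensities) < 16L) {
    abort("image must be at least 16 x 16 pixels.")
  }
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  structure(
    intensities,
    pixel_size_um = pixel_size_um,
    channel = channel,
    time_s = time_s,
    class = c("image_plane", "matrix", "array")
  )
}

#' @rdname image_plane
#' @param x An `image_plane` (or plain matrix; falls back to `default`).
#' @param default Pixel size to assume for bare matrices.
#' @export
pixel_size <- function(x, default = 0.135) {
  attr(x, "pixel_size_um") %||% default
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf(
    "<image_plane> %d x %d px, %.3f um/px, channel = %s, range [%.3g, %.3g]\n",
    nrow(x), ncol(x), pixel_size(x), attr(x, "channel") %||% "?",
    min(x), max(x)
  ))
  invisible(x)
}

# strip image_plane attributes down to a plain matrix (EBImage interop)
as_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
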