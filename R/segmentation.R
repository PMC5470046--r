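#' Segment the cell outline
#'
#' Produces a single connected boolean cell mask from the marker (or a
#' cytoplasmic stain) channel: Gaussian smoothing, Otsu threshold on
#' min-max-normalised intensities (hence invariant to gain and offset),
#' largest connected component, hole filling.
#'
#' @param plane An [image_plane()] or numeric matrix.
#' @param smooth_sigma_px Smoothing sd in pixels before thresholding.
#' @return Logical matrix, `TRUE` inside the cell.
#' @export
segment_cell <- function(plane, smooth_sigma_px = 4) {
  x <- as_matrix(plane)
  if (any(!is.finite(x))) abort("image contains non-finite pixels.")
  rng <- range(x)
  if (diff(rng) == 0) abort("cannot segment a constant image into a cell mask.")
  sm <- if (smooth_sigma_px > 0) as_matrix(EBImage::gblur(x, smooth_sigma_px)) else x
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > thr
  lab <- as_matrix(EBImage::bwlabel(mask))
  if (max(lab) == 0L) abort("cell segmentation produced an empty mask.")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- as_matrix(EBImage::fillHull(matrix(as.integer(mask), nrow(mask)))) > 0
  mask
}

# Crofton 4-direction perimeter of a logical mask: pi/8 times the transition
# counts along rows, columns and both diagonals (diagonal families weighted
# by their 1/sqrt(2) line spacing). Matches skimage's perimeter_crofton
# (directions = 4) on reference shapes.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  n_h <- sum(abs(m[, -1] - m[, -nc]))
  n_v <- sum(abs(m[-1, ] - m[-nr, ]))
  n_d1 <- sum(abs(m[-1, -1] - m[-nr, -nc]))
  n_d2 <- sum(abs(m[-1, -nc] - m[-nr, -1]))
  pi / 8 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Segment granules on the marker channel
#'
#' Detects granule-scale blobs with a difference-of-Gaussians band-pass,
#' thresholds the response inside the cell mask (Otsu on the normalised
#' response, so segmentation is invariant to multiplying the image by any
#' positive gain), fills holes, labels 4-connected components, and filters
#' them by area. Labels are renumbered in raster-scan order of each
#' component's first pixel, so output is deterministic.
#'
#' @param marker The granule-defining [image_plane()] (e.g. FUS-mCherry).
#' @param cell_mask Logical matrix from [segment_cell()]; computed from
#'   `marker` when `NULL`.
#' @param smooth_sigma_px Pre-smoothing sd, pixels.
#' @param dog_sigma_px Length-2 `(narrow, wide)` DoG sd pair, pixels; the
#'   band-pass centre should match the granule radius scale.
#' @param threshold_mode `"otsu"` (default) or a numeric quantile in (0, 1)
#'   of the in-cell response to threshold at.
#' @param rel_peak_frac Components whose peak band-pass response is below
#'   this fraction of the global peak are dropped (suppresses noise specks;
#'   gain-invariant).
#' @param min_area_px,max_area_px Area gates in pixels; `max_area_px = NULL`
#'   defaults to 5% of the cell-mask area.
#' @return A `granule_labels` object: list with `labels` (integer matrix,
#'   0 = background), `cell_mask`, and `n` (granule count). A blank or
#'   constant image yields zero granules, not an error.
#' @examples
#' sc <- render_scene(scene_spec(n_granules = 5, seed = 2))
#' gl <- segment_granules(sc$marker, sc$cell_mask)
#' gl$n
#' @export
segment_granules <- function(marker, cell_mask = NULL,
                             smooth_sigma_px = 0.5,
                             dog_sigma_px = c(1, 8),
                             threshold_mode = "otsu",
                             rel_peak_frac = 0.25,
                             min_area_px = 4,
                             max_area_px = NULL) {
  x <- as_matrix(marker)
  if (any(!is.finite(x))) abort("image contains non-finite pixels.")
  if (is.null(cell_mask)) cell_mask <- segment_cell(marker)
  if (is.null(max_area_px)) max_area_px <- 0.05 * sum(cell_mask)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(x), ncol(x)),
                   cell_mask = cell_mask, n = 0L),
              class = "granule_labels")
  }
  if (diff(range(x)) == 0) return(empty())
  if (smooth_sigma_px > 0) x <- as_matrix(EBImage::gblur(x, smooth_sigma_px))
  dog <- as_matrix(EBImage::gblur(x, dog_sigma_px[1])) -
    as_matrix(EBImage::gblur(x, dog_sigma_px[2]))
  vals <- dog[cell_mask]
  if (length(vals) == 0L || diff(range(vals)) == 0) return(empty())
  dn <- (dog - min(vals)) / (max(vals) - min(vals))
  thr <- if (identical(threshold_mode, "otsu")) {
    EBImage::otsu(EBImage::Image(pmin(pmax(dn, 0), 1)))
  } else if (is.numeric(threshold_mode)) {
    stats::quantile(dn[cell_mask], threshold_mode, names = FALSE)
  } else {
    abort("`threshold_mode` must be \"otsu\" or a numeric quantile.")
  }
  mask <- dn > thr & cell_mask
  if (!any(mask)) return(empty())
  mask <- as_matrix(EBImage::fillHull(matrix(as.integer(mask), nrow(mask)))) > 0
  mask <- mask & cell_mask
  lab <- as_matrix(EBImage::bwlabel(mask))
  n0 <- max(lab)
  if (n0 == 0L) return(empty())
  areas <- tabulate(lab[lab > 0L], nbins = n0)
  peaks <- vapply(seq_len(n0), function(k) max(dn[lab == k]), numeric(1))
  keep <- which(areas >= min_area_px & areas <= max_area_px &
                  peaks >= rel_peak_frac * max(peaks))
  if (length(keep) == 0L) return(empty())
  # deterministic relabel: raster-scan (row-major) order of first pixel
  first_idx <- vapply(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    min((w[, 1] - 1) * ncol(lab) + w[, 2])
  }, numeric(1))
  keep <- keep[order(first_idx)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  structure(list(labels = out, cell_mask = cell_mask, n = length(keep)),
            class = "granule_labels")
}

#' @export
print.granule_labels <- function(x, ...) {
  cat(sprintf("<granule_labels> %d granules in %d x %d px\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Measure granule geometry
#'
#' Computes, per labelled granule: pixel area, physical area, centroid,
#' Crofton-estimated perimeter, and circularity
#' \eqn{C = 4\pi A / P^2} (1 for a disk; digitisation can push slightly
#' above 1 for very small regions).
#'
#' @param regions A `granule_labels` object from [segment_granules()], or a
#'   bare integer label matrix.
#' @param pixel_size_um Pixel size for `area_um2`.
#' @return Tibble: `granule`, `row`, `col` (centroid), `area_px`,
#'   `area_um2`, `perimeter_px`, `circularity`.
#' @export
measure_geometry <- function(regions, pixel_size_um = 0.135) {
  lab <- if (inherits(regions, "granule_labels")) regions$labels else regions
  n <- max(lab)
  if (n == 0L) {
    return(tibble(granule = integer(), row = numeric(), col = numeric(),
                  area_px = numeric(), area_um2 = numeric(),
                  perimeter_px = numeric(), circularity = numeric()))
  }
  purrr::map_dfr(seq_len(n), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    sub <- lab[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]), drop = FALSE]
    P <- crofton_perimeter(sub == k)
    A <- nrow(w)
    tibble(granule = k, row = mean(w[, 1]), col = mean(w[, 2]),
           area_px = A, area_um2 = A * pixel_size_um^2,
           perimeter_px = P, circularity = 4 * pi * A / P^2)
  })
}
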