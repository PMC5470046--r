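#' Specify a synthetic two-channel granule scene
#'
#' Describes one cell containing diffraction-blurred stress granules imaged
#' in two co-registered channels: a *marker* channel that defines the
#' granules (e.g. FUS-mCherry or G3BP) and a *probe* channel whose
#' per-granule enrichment over the cytoplasm is the controlled ground truth.
#' Granules are uniform disks convolved with a Gaussian PSF; the camera model
#' is Poisson shot noise on photon counts plus additive Gaussian read noise
#' and a constant offset.
#'
#' Ground-truth enrichment is defined in the image plane: the disk amplitude
#' is calibrated so that, before noise, the mean probe intensity over the
#' true disk divided by the cytoplasmic probe level equals
#' `probe_enrichment_ratios` for each granule, PSF included.
#'
#' @param image_shape Integer `(rows, cols)` of the field of view.
#' @param pixel_size_um Pixel size, micrometres per pixel. The default 0.135
#'   makes a 20 px square span 2.7 um, the bleach-spot geometry used in the
#'   FRAP assay this generator feeds.
#' @param cell_center,cell_axes Ellipse centre and semi-axes of the cell
#'   outline, pixels. Defaults centre the cell and fill ~84% of each axis.
#' @param n_granules Number of granules to place (may be 0).
#' @param granule_radius_px Length-2 numeric `(mean, sd)` of granule radii in
#'   pixels. Radii are truncated below at 2 px.
#' @param marker_granule_level Mean marker intensity inside a granule, a.u.
#' @param marker_cytoplasm_level,probe_cytoplasm_level Cytoplasmic levels, a.u.
#' @param probe_enrichment_ratios True per-granule probe enrichment ratios
#'   (recycled to `n_granules`); 1 means no enrichment.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels (0 = no blur).
#' @param gain Photon gain, a.u. per photon; 0 disables shot noise.
#' @param read_noise_sd Gaussian read-noise standard deviation, a.u.
#' @param background_offset Constant camera offset added everywhere, a.u.
#' @param noise If `FALSE`, both shot and read noise are disabled (the
#'   offset is still added).
#' @param seed Integer RNG seed; identical (spec, seed) pairs reproduce
#'   bit-identical scenes.
#' @return A `scene_spec` list.
#' @seealso [render_scene()]
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       pixel_size_um = 0.135,
                       cell_center = (image_shape + 1) / 2,
                       cell_axes = 0.42 * image_shape,
                       n_granules = 12L,
                       granule_radius_px = c(5, 1),
                       marker_granule_level = 400,
                       marker_cytoplasm_level = 100,
                       probe_cytoplasm_level = 100,
                       probe_enrichment_ratios = 1,
                       psf_sigma_px = 1,
                       gain = 2,
                       read_noise_sd = 2,
                       background_offset = 10,
                       noise = TRUE,
                       seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape),
    pixel_size_um = pixel_size_um,
    cell_center = as.numeric(cell_center),
    cell_axes = as.numeric(cell_axes),
    n_granules = as.integer(n_granules),
    granule_radius_px = as.numeric(granule_radius_px),
    marker_granule_level = marker_granule_level,
    marker_cytoplasm_level = marker_cytoplasm_level,
    probe_cytoplasm_level = probe_cytoplasm_level,
    probe_enrichment_ratios = as.numeric(probe_enrichment_ratios),
    psf_sigma_px = psf_sigma_px,
    gain = if (isTRUE(noise)) gain else 0,
    read_noise_sd = if (isTRUE(noise)) read_noise_sd else 0,
    background_offset = background_offset,
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (length(spec$image_shape) != 2L || any(spec$image_shape < 16L)) {
    abort("`image_shape` must be two integers, each >= 16.")
  }
  stopifnot_scalar_number(spec$pixel_size_um, "pixel_size_um", lower = 1e-6)
  if (spec$n_granules < 0L) abort("`n_granules` must be >= 0.")
  if (length(spec$granule_radius_px) != 2L || spec$granule_radius_px[1] <= 0 ||
      spec$granule_radius_px[2] < 0) {
    abort("`granule_radius_px` must be (mean > 0, sd >= 0).")
  }
  for (f in c("marker_granule_level", "marker_cytoplasm_level",
              "probe_cytoplasm_level")) {
    stopifnot_scalar_number(spec[[f]], f, lower = 1e-9)
  }
  if (any(spec$probe_enrichment_ratios <= 0)) {
    abort("`probe_enrichment_ratios` must all be > 0.")
  }
  stopifnot_scalar_number(spec$psf_sigma_px, "psf_sigma_px", lower = 0)
  stopifnot_scalar_number(spec$gain, "gain", lower = 0)
  stopifnot_scalar_number(spec$read_noise_sd, "read_noise_sd", lower = 0)
  stopifnot_scalar_number(spec$background_offset, "background_offset", lower = 0)
  invisible(spec)
}

# boolean ellipse raster; pixel centres at integer coordinates
ellipse_mask <- function(shape, center, axes) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((rows - center[1]) / axes[1])^2 + ((cols - center[2]) / axes[2])^2 <= 1
}

disk_mask <- function(shape, center, radius) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# Fraction of a blurred unit disk's amplitude retained, averaged over the
# true disk: blur moves flux across the rim, so the disk mean of a blurred
# disk is < 1. Used to pre-compensate amplitudes so post-blur truth is exact.
disk_psf_retention <- function(radius, sigma) {
  if (sigma <= 0) return(1)
  pad <- ceiling(radius + 3 * sigma + 3)
  n <- 2L * pad + 1L
  ctr <- c(pad + 1, pad + 1)
  d <- disk_mask(c(n, n), ctr, radius)
  b <- as_matrix(EBImage::gblur(matrix(as.numeric(d), n, n), sigma = sigma))
  mean(b[d])
}

# Rejection-sample non-overlapping granule centres inside the cell ellipse,
# keeping a safety margin from the cell boundary so PSF tails of the cell
# edge never reach a granule's surround. Consumes RNG (caller seeds).
place_granules <- function(spec, min_sep_px = 4) {
  n <- spec$n_granules
  if (n == 0L) {
    return(tibble(granule = integer(), row = numeric(), col = numeric(),
                  radius_px = numeric()))
  }
  radii <- pmax(2, rnorm(n, spec$granule_radius_px[1], spec$granule_radius_px[2]))
  margin <- radii + 3 * spec$psf_sigma_px + 8 # room for surround annulus too
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 4000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0(
        "granule placement failed: could not fit ", n, " granules of radius ~",
        signif(spec$granule_radius_px[1], 3), " px inside the cell. ",
        "Reduce `n_granules` or `granule_radius_px`, or enlarge the cell."
      ), class = "sgquant_placement_error")
    }
    i <- placed + 1L
    ax <- spec$cell_axes - margin[i]
    if (any(ax <= 0)) {
      abort("granule placement failed: granule larger than the cell.",
            class = "sgquant_placement_error")
    }
    r <- spec$cell_center[1] + runif(1, -ax[1], ax[1])
    c <- spec$cell_center[2] + runif(1, -ax[2], ax[2])
    if (((r - spec$cell_center[1]) / ax[1])^2 +
        ((c - spec$cell_center[2]) / ax[2])^2 > 1) next
    if (placed > 0L) {
      sep <- sqrt((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2)
      if (any(sep < radii[seq_len(placed)] + radii[i] + min_sep_px)) next
    }
    rows[i] <- r; cols[i] <- c
    placed <- i
  }
  tibble(granule = seq_len(n), row = rows, col = cols, radius_px = radii)
}

# Render ideal (noise-free, offset-free) marker/probe planes for granules at
# given positions. `positions` needs columns row, col, radius_px and, for the
# probe, true_ratio. Shared by render_scene() and render_timelapse().
render_ideal_planes <- function(spec, positions, cell_mask) {
  shape <- spec$image_shape
  marker <- ifelse(cell_mask, spec$marker_cytoplasm_level, 0)
  probe <- ifelse(cell_mask, spec$probe_cytoplasm_level, 0)
  if (nrow(positions) > 0L) {
    for (i in seq_len(nrow(positions))) {
      rho <- disk_psf_retention(positions$radius_px[i], spec$psf_sigma_px)
      d <- disk_mask(shape, c(positions$row[i], positions$col[i]),
                     positions$radius_px[i])
      marker[d] <- marker[d] +
        (spec$marker_granule_level - spec$marker_cytoplasm_level) / rho
      probe[d] <- probe[d] +
        (positions$true_ratio[i] - 1) * spec$probe_cytoplasm_level / rho
    }
  }
  if (spec$psf_sigma_px > 0) {
    marker <- as_matrix(EBImage::gblur(marker, sigma = spec$psf_sigma_px))
    probe <- as_matrix(EBImage::gblur(probe, sigma = spec$psf_sigma_px))
  }
  list(marker = marker, probe = probe)
}

# camera model: Poisson shot noise on photons, then offset + read noise.
# Consumes RNG (caller seeds).
apply_camera <- function(ideal, gain, read_noise_sd, offset) {
  out <- ideal
  if (gain > 0) {
    out <- gain * rpois(length(out), pmax(out, 0) / gain)
    dim(out) <- dim(ideal)
  }
  out <- out + offset
  if (read_noise_sd > 0) {
    out <- out + rnorm(length(out), 0, read_noise_sd)
    dim(out) <- dim(ideal)
  }
  pmax(out, 0)
}

#' Render a synthetic two-channel granule scene
#'
#' Places non-overlapping granules inside an elliptical cell, renders
#' PSF-blurred marker and probe planes, applies the camera noise model, and
#' returns the planes together with the ground-truth granule table.
#'
#' @param spec A [scene_spec()].
#' @return An `sg_scene` list with elements `marker` and `probe`
#'   ([image_plane()]s), `marker_ideal`/`probe_ideal` (noise- and offset-free
#'   planes, for oracle measurements), `cell_mask` (logical matrix), `truth`
#'   (tibble: granule, row, col, radius_px, true_ratio), and `spec`.
#' @examples
#' sc <- render_scene(scene_spec(n_granules = 4, probe_enrichment_ratios = 2,
#'                               seed = 7))
#' sc$truth
#' @export
render_scene <- function(spec) {
  validate_scene_spec(spec)
  local_seed(spec$seed, {
    truth <- place_granules(spec)
    truth$true_ratio <- if (nrow(truth) > 0L) {
      rep_len(spec$probe_enrichment_ratios, nrow(truth))
    } else numeric()
    cell_mask <- ellipse_mask(spec$image_shape, spec$cell_center, spec$cell_axes)
    ideal <- render_ideal_planes(spec, truth, cell_mask)
    marker <- apply_camera(ideal$marker, spec$gain, spec$read_noise_sd,
                           spec$background_offset)
    probe <- apply_camera(ideal$probe, spec$gain, spec$read_noise_sd,
                          spec$background_offset)
    structure(
      list(
        marker = image_plane(marker, spec$pixel_size_um, "marker"),
        probe = image_plane(probe, spec$pixel_size_um, "probe"),
        marker_ideal = ideal$marker,
        probe_ideal = ideal$probe,
        cell_mask = cell_mask,
        truth = truth,
        spec = spec
      ),
      class = "sg_scene"
    )
  })
}

#' @export
print.sg_scene <- function(x, ...) {
  cat(sprintf("<sg_scene> %d x %d px, %d granules, seed %d\n",
              nrow(x$marker), ncol(x$marker), nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Render a paired pre/post RNase-injection scene
#'
#' Emulates the RNase microinjection experiment: the post-injection frame
#' re-renders the same granules with radii scaled so that the total granule
#' area is `area_remaining_frac` of the pre-injection area. RNA-dependent
#' (liquid-like) granules dissolve almost completely (fraction ~0.09 in the
#' assay this emulates); aberrant granules persist (~0.88).
#'
#' @param spec A [scene_spec()] for the pre-injection scene.
#' @param area_remaining_frac Target fraction of total granule area remaining
#'   after injection, in (0, 1].
#' @return List with `pre` and `post` `sg_scene` objects.
#' @export
render_rnase_pair <- function(spec, area_remaining_frac = 0.88) {
  stopifnot_scalar_number(area_remaining_frac, "area_remaining_frac",
                          lower = 1e-6, upper = 1)
  pre <- render_scene(spec)
  post_spec <- spec
  post_spec$seed <- spec$seed + 1L # fresh noise, same geometry
  local_seed(post_spec$seed, {
    truth <- pre$truth
    truth$radius_px <- truth$radius_px * sqrt(area_remaining_frac)
    ideal <- render_ideal_planes(post_spec, truth, pre$cell_mask)
    marker <- apply_camera(ideal$marker, post_spec$gain, post_spec$read_noise_sd,
                           post_spec$background_offset)
    probe <- apply_camera(ideal$probe, post_spec$gain, post_spec$read_noise_sd,
                          post_spec$background_offset)
    post <- structure(
      list(
        marker = image_plane(marker, spec$pixel_size_um, "marker"),
        probe = image_plane(probe, spec$pixel_size_um, "probe"),
        marker_ideal = ideal$marker,
        probe_ideal = ideal$probe,
        cell_mask = pre$cell_mask,
        truth = truth,
        spec = post_spec
      ),
      class = "sg_scene"
    )
    list(pre = pre, post = post)
  })
}
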