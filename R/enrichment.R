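#' Estimate the camera background of a plane
#'
#' Default background for enrichment ratios: the mode (kernel-density peak)
#' of the pixels outside the cell mask, i.e. the camera offset. Returns 0
#' when there are no extracellular pixels.
#'
#' @param plane Image plane or matrix.
#' @param cell_mask Logical matrix, `TRUE` inside the cell.
#' @return Scalar background level, a.u.
#' @export
estimate_background <- function(plane, cell_mask) {
  outside <- as_matrix(plane)[!cell_mask]
  if (length(outside) < 16L) return(0)
  density_mode(outside)
}

# inside/surround pixel sets for one granule, on a local crop.
# surround = annulus from `gap` to `gap + width` outside the granule
# boundary, clipped to the cell mask, excluding every granule's pixels.
granule_surround_masks <- function(labels, cell_mask, id, gap, width) {
  w <- which(labels == id, arr.ind = TRUE)
  m <- gap + width + 1L
  r0 <- max(1L, min(w[, 1]) - m); r1 <- min(nrow(labels), max(w[, 1]) + m)
  c0 <- max(1L, min(w[, 2]) - m); c1 <- min(ncol(labels), max(w[, 2]) + m)
  lab_c <- labels[r0:r1, c0:c1, drop = FALSE]
  cell_c <- cell_mask[r0:r1, c0:c1, drop = FALSE]
  inside <- lab_c == id
  brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  dil_outer <- as_matrix(EBImage::dilate(inside, brush(gap + width))) > 0
  dil_inner <- as_matrix(EBImage::dilate(inside, brush(gap))) > 0
  surround <- dil_outer & !dil_inner & cell_c & lab_c == 0L
  list(inside = inside, surround = surround,
       window = c(r0, r1, c0, c1))
}

#' Per-granule relative enrichment ratio
#'
#' The central statistic of the high-content granule assay: the mean
#' fluorescence intensity inside a granule divided by the mean intensity in
#' a region surrounding it. The surround is an annulus from
#' `surround_gap_px` to `surround_gap_px + surround_width_px` outside the
#' granule boundary, clipped to the cell mask and excluding all granule
#' pixels (so neighbouring granules never contaminate it). An optional
#' background is subtracted from both means; the ratio is invariant to
#' multiplicative gain, and background subtraction restores invariance to
#' additive offsets.
#'
#' @param regions `granule_labels` from [segment_granules()].
#' @param channel The [image_plane()] to measure.
#' @param granule_id Integer label of the granule.
#' @param surround_gap_px,surround_width_px Annulus geometry, pixels.
#' @param background Scalar background (a.u.), `"auto"` for
#'   [estimate_background()], or `NULL`/0 for none.
#' @return One-row tibble: `granule`, `inside_mean`, `surround_mean`,
#'   `ratio`, `measurable`. `ratio` is `NA` (with `measurable = FALSE`)
#'   when the surround is empty or its background-subtracted mean is <= 0.
#' @export
enrichment_ratio <- function(regions, channel, granule_id,
                             surround_gap_px = 2, surround_width_px = 4,
                             background = "auto") {
  bg <- resolve_background(background, channel, regions$cell_mask)
  measure_one_granule(regions$labels, regions$cell_mask, as_matrix(channel),
                      granule_id, surround_gap_px, surround_width_px, bg)
}

resolve_background <- function(background, plane, cell_mask) {
  if (is.null(background)) return(0)
  if (identical(background, "auto")) return(estimate_background(plane, cell_mask))
  stopifnot_scalar_number(background, "background", lower = 0)
  background
}

measure_one_granule <- function(labels, cell_mask, chan, id, gap, width, bg) {
  ms <- granule_surround_masks(labels, cell_mask, id, gap, width)
  w <- ms$window
  chan_c <- chan[w[1]:w[2], w[3]:w[4], drop = FALSE]
  inside_mean <- mean(chan_c[ms$inside]) - bg
  n_sur <- sum(ms$surround)
  if (n_sur == 0L) {
    return(tibble(granule = id, inside_mean = inside_mean,
                  surround_mean = NA_real_, ratio = NA_real_,
                  measurable = FALSE))
  }
  surround_mean <- mean(chan_c[ms$surround]) - bg
  if (surround_mean <= 0) {
    return(tibble(granule = id, inside_mean = inside_mean,
                  surround_mean = surround_mean, ratio = NA_real_,
                  measurable = FALSE))
  }
  tibble(granule = id, inside_mean = inside_mean,
         surround_mean = surround_mean,
         ratio = inside_mean / surround_mean, measurable = TRUE)
}

#' Measure geometry and per-channel enrichment for every granule
#'
#' The workhorse of the quantification stage: combines [measure_geometry()]
#' with [enrichment_ratio()] across one or more channels, returning one row
#' per granule ready for [classify_enriched()], [enrichment_correlation()]
#' and plotting.
#'
#' @param regions `granule_labels` from [segment_granules()].
#' @param channels Named list of [image_plane()]s, e.g.
#'   `list(marker = ..., probe = ...)`.
#' @param surround_gap_px,surround_width_px Annulus geometry, pixels.
#' @param background Per-channel background: `"auto"` (default), a number,
#'   `NULL`, or a named list keyed like `channels`.
#' @param pixel_size_um Pixel size; defaults to the first channel's.
#' @return Tibble with geometry columns plus, for each channel `ch`:
#'   `ch_inside`, `ch_surround`, `ch_ratio`, `ch_measurable`.
#' @examples
#' sc <- render_scene(scene_spec(n_granules = 4, probe_enrichment_ratios = 3,
#'                               seed = 5))
#' gl <- segment_granules(sc$marker, sc$cell_mask)
#' gr <- measure_granules(gl, list(marker = sc$marker, probe = sc$probe))
#' gr[, c("granule", "area_px", "circularity", "probe_ratio")]
#' @export
measure_granules <- function(regions, channels,
                             surround_gap_px = 2, surround_width_px = 4,
                             background = "auto",
                             pixel_size_um = NULL) {
  if (!inherits(regions, "granule_labels")) {
    abort("`regions` must come from segment_granules().")
  }
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    abort("`channels` must be a named list of image planes.")
  }
  if (is.null(pixel_size_um)) pixel_size_um <- pixel_size(channels[[1]])
  geom <- measure_geometry(regions, pixel_size_um)
  if (regions$n == 0L) return(geom)
  for (ch in names(channels)) {
    bg_spec <- if (is.list(background)) background[[ch]] %||% "auto" else background
    bg <- resolve_background(bg_spec, channels[[ch]], regions$cell_mask)
    chan <- as_matrix(channels[[ch]])
    meas <- purrr::map_dfr(seq_len(regions$n), function(k) {
      measure_one_granule(regions$labels, regions$cell_mask, chan, k,
                          surround_gap_px, surround_width_px, bg)
    })
    geom[[paste0(ch, "_inside")]] <- meas$inside_mean
    geom[[paste0(ch, "_surround")]] <- meas$surround_mean
    geom[[paste0(ch, "_ratio")]] <- meas$ratio
    geom[[paste0(ch, "_measurable")]] <- meas$measurable
  }
  geom
}

#' Classify granules as enriched against a threshold
#'
#' Counts granules whose enrichment ratio strictly exceeds the threshold
#' (the assay's convention is "ratio > 1.4"; a stricter 1.5 is used for
#' time-course classification). Respects `dplyr` grouping on the input, so
#' per-condition or per-time-point summaries fall out of `group_by()`.
#'
#' @param table Tibble with a ratio column (e.g. from [measure_granules()]).
#' @param threshold Enrichment threshold \eqn{\tau}; default 1.4.
#' @param ratio_col Name of the ratio column; defaults to `"probe_ratio"`
#'   if present, else `"ratio"`.
#' @return Tibble (one row per group) with `threshold`, `n_granules`
#'   (granules with a finite ratio), `n_enriched`, `fraction_enriched`.
#' @examples
#' classify_enriched(tibble::tibble(probe_ratio = c(1.39, 1.40, 1.41)))
#' @export
classify_enriched <- function(table, threshold = 1.4, ratio_col = NULL) {
  if (is.null(ratio_col)) {
    ratio_col <- if ("probe_ratio" %in% names(table)) "probe_ratio" else "ratio"
  }
  if (!ratio_col %in% names(table)) {
    abort(sprintf("no ratio column '%s' in `table`.", ratio_col))
  }
  table |>
    dplyr::summarise(
      threshold = .env$threshold,
      n_granules = sum(is.finite(.data[[ratio_col]])),
      n_enriched = sum(.data[[ratio_col]] > threshold, na.rm = TRUE),
      fraction_enriched = ifelse(.data$n_granules > 0,
                                 .data$n_enriched / .data$n_granules, NA_real_),
      .groups = "drop"
    )
}

#' Correlate enrichment ratios across two channels
#'
#' Pearson product-moment correlation of per-granule enrichment ratios
#' between two channels, the statistic used to relate a probe's granule
#' enrichment to, e.g., ubiquitin enrichment across ~1,000 granules.
#'
#' @param table Tibble from [measure_granules()].
#' @param col_a,col_b Ratio column names.
#' @return One-row tibble: `r`, `n`, `p_value`, `conf_low`, `conf_high`.
#'   `r` is `NA` (with a warning) if either variable has zero variance or
#'   fewer than 3 complete pairs exist.
#' @export
enrichment_correlation <- function(table, col_a = "marker_ratio",
                                   col_b = "probe_ratio") {
  a <- table[[col_a]]; b <- table[[col_b]]
  if (is.null(a) || is.null(b)) abort("ratio columns not found in `table`.")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L || sd(a) == 0 || sd(b) == 0) {
    warn("correlation undefined: fewer than 3 pairs or zero variance.")
    return(tibble(r = NA_real_, n = length(a), p_value = NA_real_,
                  conf_low = NA_real_, conf_high = NA_real_))
  }
  ct <- cor.test(a, b)
  tibble(r = unname(ct$estimate), n = length(a), p_value = ct$p.value,
         conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}

#' Fraction of enriched granules over a time course
#'
#' Applies [classify_enriched()] per time point (and per replicate when a
#' replicate column is given), then summarises the replicate fractions as
#' mean and SEM. With a single replicate the SEM is reported as `NA`
#' (absent), never 0.
#'
#' @param table Tibble of granule rows with a time column.
#' @param threshold Enrichment threshold.
#' @param time_col,replicate_col Column names; `replicate_col = NULL` treats
#'   each time point as one replicate.
#' @param ratio_col Passed to [classify_enriched()].
#' @return Tibble: time column, `n_replicates`, `fraction_enriched`
#'   (mean over replicates), `sem`.
#' @export
timecourse_fraction <- function(table, threshold = 1.5,
                                time_col = "time", replicate_col = NULL,
                                ratio_col = NULL) {
  if (!time_col %in% names(table)) {
    abort(sprintf("no time column '%s' in `table`.", time_col))
  }
  if (dplyr::n_distinct(table[[time_col]]) < 2L) {
    abort("a time course needs at least 2 time points.")
  }
  tau <- threshold
  keys <- c(time_col, replicate_col)
  per_rep <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    classify_enriched(threshold = tau, ratio_col = ratio_col)
  per_rep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(time_col))) |>
    dplyr::summarise(
      threshold = .env$tau,
      n_replicates = dplyr::n(),
      sem = sem(.data$fraction_enriched),
      fraction_enriched = mean(.data$fraction_enriched, na.rm = TRUE),
      .groups = "drop"
    )
}
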