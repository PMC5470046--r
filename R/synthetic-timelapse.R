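#' Script a granule time-lapse
#'
#' A time-lapse script is the ground truth for the dynamics analyses: a
#' waypoint table giving every granule's position and radius at every frame
#' it exists, an event table of scripted fusion/fission/disappearance, and
#' an optional per-cell complete-disassembly frame.
#'
#' @param waypoints Tibble with columns `frame` (1-based), `id`, `row`,
#'   `col`, `radius_px` and optionally `true_ratio` (probe enrichment,
#'   default 1).
#' @param events Tibble with columns `frame`, `kind` (one of `"fusion"`,
#'   `"fission"`, `"disappear"`, `"shrink"`), `parents` and `children`
#'   (list-columns of granule ids), or `NULL`.
#' @param disassembly_frame Frame at which the cell's last granule is gone,
#'   or `NA` if granules persist to the movie end (censored).
#' @param n_frames Movie length in frames; defaults to the last waypoint
#'   frame (set it higher to append empty frames, e.g. after disassembly).
#' @param area_tol Relative tolerance for area conservation across
#'   fusion/fission events (children disk area vs parents).
#' @return A validated `timelapse_script` list with `n_frames` filled in.
#' @seealso [render_timelapse()], [script_fusion()], [script_fission()]
#' @export
timelapse_script <- function(waypoints, events = NULL, disassembly_frame = NA,
                             n_frames = NULL, area_tol = 0.1) {
  waypoints <- as_tibble(waypoints)
  need <- c("frame", "id", "row", "col", "radius_px")
  if (!all(need %in% names(waypoints))) {
    abort(paste("`waypoints` needs columns:", paste(need, collapse = ", ")))
  }
  if (!"true_ratio" %in% names(waypoints)) waypoints$true_ratio <- 1
  if (nrow(waypoints) == 0L) abort("`waypoints` must be non-empty.")
  if (anyDuplicated(waypoints[c("frame", "id")])) {
    abort("`waypoints` has duplicate (frame, id) rows.")
  }
  n_frames <- max(n_frames %||% 0L, max(waypoints$frame))
  if (is.null(events)) {
    events <- tibble(frame = integer(), kind = character(),
                     parents = list(), children = list())
  }
  events <- as_tibble(events)
  ids_at <- function(f) waypoints$id[waypoints$frame == f]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    kind <- ev$kind
    parents <- ev$parents[[1]]
    children <- ev$children[[1]]
    if (!kind %in% c("fusion", "fission", "disappear", "shrink")) {
      abort(sprintf("unknown event kind '%s'.", kind))
    }
    if (!all(parents %in% ids_at(ev$frame - 1L))) {
      abort(sprintf("event %d: parents missing at frame %d.", i, ev$frame - 1L))
    }
    if (kind %in% c("fusion", "fission")) {
      if (kind == "fusion" && (length(parents) < 2L || length(children) != 1L)) {
        abort(sprintf("event %d: fusion needs >= 2 parents and 1 child.", i))
      }
      if (kind == "fission" && (length(parents) != 1L || length(children) < 2L)) {
        abort(sprintf("event %d: fission needs 1 parent and >= 2 children.", i))
      }
      if (!all(children %in% ids_at(ev$frame))) {
        abort(sprintf("event %d: children missing at frame %d.", i, ev$frame))
      }
      r_par <- waypoints$radius_px[waypoints$frame == ev$frame - 1L &
                                     waypoints$id %in% parents]
      r_chi <- waypoints$radius_px[waypoints$frame == ev$frame &
                                     waypoints$id %in% children]
      if (abs(sum(r_chi^2) - sum(r_par^2)) > area_tol * sum(r_par^2)) {
        abort(sprintf("event %d: child area deviates from parent area by > %g%%.",
                      i, 100 * area_tol))
      }
    }
  }
  structure(
    list(waypoints = waypoints, events = events,
         disassembly_frame = disassembly_frame, n_frames = n_frames),
    class = "timelapse_script"
  )
}

#' Convenience script builders
#'
#' `script_static()` holds granules in place; `script_drift()` moves them at
#' constant velocity; `script_fusion()` brings two granules together until
#' they merge (child area = sum of parents); `script_fission()` splits one
#' granule into two that then separate; `script_disassembly()` removes all
#' granules at a given frame.
#'
#' @param n_frames Movie length in frames.
#' @param positions Tibble with `id`, `row`, `col`, `radius_px`.
#' @param velocity Length-2 per-frame displacement `(d_row, d_col)`, pixels.
#' @param fuse_frame,split_frame Frame at which the event happens.
#' @param approach_gap_px Minimum edge-to-edge gap maintained until the
#'   event frame, so segmentation cannot merge the disks early.
#' @param disassembly_frame Frame from which the cell has no granules.
#' @return A [timelapse_script()].
#' @name script_builders
NULL

#' @rdname script_builders
#' @export
script_static <- function(n_frames, positions) {
  wp <- tidyr::crossing(frame = seq_len(n_frames), as_tibble(positions))
  timelapse_script(wp)
}

#' @rdname script_builders
#' @export
script_drift <- function(n_frames, positions, velocity = c(2, 0)) {
  positions <- as_tibble(positions)
  wp <- purrr::map_dfr(seq_len(n_frames), function(f) {
    dplyr::mutate(positions,
                  frame = f,
                  row = .data$row + (f - 1) * velocity[1],
                  col = .data$col + (f - 1) * velocity[2])
  })
  timelapse_script(wp)
}

#' @rdname script_builders
#' @param center Midpoint `(row, col)` of the event, pixels.
#' @param radii Parent radii (fusion) or child radii (fission), length 2.
#' @param start_sep_px Initial centre-to-centre separation, pixels.
#' @export
script_fusion <- function(n_frames, fuse_frame, center, radii = c(4, 4),
                          start_sep_px = 30, approach_gap_px = 4) {
  stopifnot(fuse_frame >= 3L, fuse_frame <= n_frames)
  min_sep <- sum(radii) + approach_gap_px
  # linear approach from start_sep to min_sep over frames 1..fuse_frame-1
  sep <- seq(start_sep_px, min_sep, length.out = fuse_frame - 1L)
  wp <- purrr::map_dfr(seq_len(fuse_frame - 1L), function(f) {
    tibble(frame = f, id = c(1L, 2L),
           row = center[1],
           col = center[2] + c(-0.5, 0.5) * sep[f],
           radius_px = radii)
  })
  child <- tibble(frame = seq(fuse_frame, n_frames), id = 3L,
                  row = center[1], col = center[2],
                  radius_px = sqrt(sum(radii^2)))
  ev <- tibble(frame = fuse_frame, kind = "fusion",
               parents = list(c(1L, 2L)), children = list(3L))
  timelapse_script(dplyr::bind_rows(wp, child), ev)
}

#' @rdname script_builders
#' @param end_sep_px Final centre-to-centre separation of the children.
#' @export
script_fission <- function(n_frames, split_frame, center, radii = c(4, 4),
                           end_sep_px = 30, approach_gap_px = 4) {
  stopifnot(split_frame >= 2L, split_frame < n_frames)
  parent_r <- sqrt(sum(radii^2))
  parent <- tibble(frame = seq_len(split_frame - 1L), id = 1L,
                   row = center[1], col = center[2], radius_px = parent_r)
  min_sep <- sum(radii) + approach_gap_px
  sep <- seq(min_sep, end_sep_px, length.out = n_frames - split_frame + 1L)
  wp <- purrr::map_dfr(seq(split_frame, n_frames), function(f) {
    s <- sep[f - split_frame + 1L]
    tibble(frame = f, id = c(2L, 3L),
           row = center[1], col = center[2] + c(-0.5, 0.5) * s,
           radius_px = radii)
  })
  ev <- tibble(frame = split_frame, kind = "fission",
               parents = list(1L), children = list(c(2L, 3L)))
  timelapse_script(dplyr::bind_rows(parent, wp), ev)
}

#' @rdname script_builders
#' @export
script_disassembly <- function(n_frames, disassembly_frame, positions) {
  positions <- as_tibble(positions)
  stopifnot(disassembly_frame >= 2L)
  wp <- tidyr::crossing(frame = seq_len(min(disassembly_frame - 1L, n_frames)),
                        positions)
  ev <- if (disassembly_frame <= n_frames) {
    tibble(frame = disassembly_frame, kind = "disappear",
           parents = list(unique(positions$id)), children = list(integer()))
  } else NULL
  timelapse_script(
    wp, ev,
    disassembly_frame = if (disassembly_frame <= n_frames) disassembly_frame else NA,
    n_frames = n_frames
  )
}

#' Render a scripted time-lapse
#'
#' Renders each frame of a [timelapse_script()] with the same optics and
#' camera model as [render_scene()], or rasterises ground-truth label images
#' directly (no PSF, no noise) for oracle runs of the tracking and
#' event-calling stages.
#'
#' @param script A [timelapse_script()].
#' @param spec A [scene_spec()] providing the cell, levels, PSF and noise;
#'   its `n_granules`/ratio fields are ignored (the script governs).
#' @param what `"planes"` for rendered marker frames, `"labels"` for
#'   ground-truth label rasters (granule id per pixel).
#' @return An `sg_timelapse` list: `frames` (list of [image_plane()]s or
#'   integer label matrices), `events` (truth event log tibble),
#'   `detections` (truth per-frame detection tibble: frame, id, row, col,
#'   area_px), `cell_mask`, `script`, `spec`.
#' @export
render_timelapse <- function(script, spec = scene_spec(),
                             what = c("planes", "labels")) {
  what <- match.arg(what)
  if (!inherits(script, "timelapse_script")) abort("`script` must be a timelapse_script.")
  validate_scene_spec(spec)
  shape <- spec$image_shape
  cell_mask <- ellipse_mask(shape, spec$cell_center, spec$cell_axes)
  wp <- script$waypoints
  retention_cache <- new.env(parent = emptyenv())
  frames <- local_seed(spec$seed, {
    lapply(seq_len(script$n_frames), function(f) {
      pos <- wp[wp$frame == f, ]
      if (what == "labels") {
        lab <- matrix(0L, shape[1], shape[2])
        for (i in seq_len(nrow(pos))) {
          d <- disk_mask(shape, c(pos$row[i], pos$col[i]), pos$radius_px[i])
          lab[d] <- pos$id[i]
        }
        return(lab)
      }
      ideal <- render_ideal_planes(spec, pos, cell_mask)
      marker <- apply_camera(ideal$marker, spec$gain, spec$read_noise_sd,
                             spec$background_offset)
      image_plane(marker, spec$pixel_size_um, "marker",
                  time_s = (f - 1) * 1)
    })
  })
  detections <- wp |>
    dplyr::transmute(frame = .data$frame, id = .data$id, row = .data$row,
                     col = .data$col, area_px = pi * .data$radius_px^2)
  events <- script$events
  if (nrow(events) > 0L) {
    # attach event locations: mean parent position just before the event
    loc <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
      par <- events$parents[[i]]
      at <- wp[wp$frame == events$frame[i] - 1L & wp$id %in% par, ]
      tibble(row = mean(at$row), col = mean(at$col))
    })
    events$row <- loc$row
    events$col <- loc$col
  } else {
    events$row <- numeric()
    events$col <- numeric()
  }
  structure(
    list(frames = frames, events = events, detections = detections,
         cell_mask = cell_mask, script = script, spec = spec),
    class = "sg_timelapse"
  )
}

#' Sample a synthetic disassembly cohort
#'
#' Draws per-cell times to complete granule disassembly from an exponential
#' distribution (constant hazard) with right-censoring at the end of the
#' observation window, the design of the live-cell recovery experiments the
#' survival analysis consumes.
#'
#' @param n_cells Number of cells.
#' @param hazard_per_min Disassembly hazard, events per minute (> 0).
#' @param censor_at_min Observation window; cells with no disassembly by
#'   this time are censored at it.
#' @param group Group label attached to every record.
#' @param seed Integer RNG seed.
#' @return Tibble of survival records: `cell`, `group`, `time_min`,
#'   `event` (TRUE = disassembly observed), `censored` (= `!event`).
#' @examples
#' sample_survival_cohort(5, hazard_per_min = 0.02, censor_at_min = 120,
#'                        seed = 1)
#' @export
sample_survival_cohort <- function(n_cells, hazard_per_min, censor_at_min,
                                   group = "cohort", seed = 1L) {
  if (n_cells < 1L) abort("`n_cells` must be >= 1.")
  stopifnot_scalar_number(hazard_per_min, "hazard_per_min", lower = 1e-12)
  stopifnot_scalar_number(censor_at_min, "censor_at_min", lower = 0)
  local_seed(seed, {
    t_true <- rexp(n_cells, rate = hazard_per_min)
    event <- t_true <= censor_at_min
    tibble(
      cell = seq_len(n_cells),
      group = group,
      time_min = pmin(t_true, censor_at_min),
      event = event,
      censored = !event
    )
  })
}
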