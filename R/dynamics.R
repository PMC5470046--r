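#' Extract per-frame granule detections
#'
#' Converts a list of segmentations (or ground-truth label rasters) into the
#' tidy detection table consumed by [track_granules()]: one row per granule
#' per frame with centroid and area.
#'
#' @param frames List of `granule_labels` objects or integer label matrices,
#'   one per movie frame.
#' @return Tibble: `frame`, `det` (within-frame detection index), `row`,
#'   `col`, `area_px`.
#' @export
granule_detections <- function(frames) {
  purrr::imap_dfr(frames, function(fr, f) {
    lab <- if (inherits(fr, "granule_labels")) fr$labels else fr
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0L) {
      return(tibble(frame = integer(), det = integer(), row = numeric(),
                    col = numeric(), area_px = numeric()))
    }
    purrr::map_dfr(seq_along(ids), function(i) {
      w <- which(lab == ids[i], arr.ind = TRUE)
      tibble(frame = as.integer(f), det = i,
             row = mean(w[, 1]), col = mean(w[, 2]),
             area_px = nrow(w))
    })
  })
}

#' Link detections into tracks
#'
#' Greedy nearest-neighbour linking between consecutive frames: all
#' candidate (track, detection) pairs within `max_link_px` are resolved
#' globally in ascending distance order; unmatched detections start new
#' tracks. Ties are broken by track id then detection position, so the
#' result is deterministic and invariant to the ordering of detections
#' within a frame. Tracks have no motion model and no gap closing: a
#' granule missed for one frame starts a new track.
#'
#' @param detections Tibble from [granule_detections()] (columns `frame`,
#'   `row`, `col`, `area_px`).
#' @param max_link_px Maximum per-frame displacement, pixels. The default
#'   scales as 3x the median granule radius inferred from the areas.
#' @return An `sg_tracks` tibble: the detections with a `track_id` column,
#'   plus a `tracks` attribute summarising each track (`track_id`,
#'   `start_frame`, `end_frame`, `n_frames`, `termination` — one of
#'   `"censored-at-movie-end"` or `"disappeared"`; [call_events()] refines
#'   disappearances into merge/split participants).
#' @export
track_granules <- function(detections, max_link_px = NULL) {
  det <- as_tibble(detections)
  if (dplyr::n_distinct(det$frame) < 2L) abort("tracking needs >= 2 frames.")
  if (is.null(max_link_px)) {
    max_link_px <- 3 * median(sqrt(det$area_px / pi))
  }
  det <- dplyr::arrange(det, .data$frame, .data$row, .data$col)
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 1L
  # seed tracks in the first frame
  i0 <- which(det$frame == frames[1])
  det$track_id[i0] <- seq_along(i0)
  next_id <- length(i0) + 1L
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]; fp <- frames[fi - 1L]
    prev <- which(det$frame == fp)
    cur <- which(det$frame == f)
    if (length(prev) > 0L && length(cur) > 0L) {
      cand <- expand.grid(p = prev, c = cur)
      cand$d <- sqrt((det$row[cand$p] - det$row[cand$c])^2 +
                       (det$col[cand$p] - det$col[cand$c])^2)
      cand <- cand[cand$d <= max_link_px, , drop = FALSE]
      cand <- cand[order(cand$d, det$track_id[cand$p],
                         det$row[cand$c], det$col[cand$c]), , drop = FALSE]
      used_p <- logical(0); used_c <- logical(0)
      taken_p <- integer(0); taken_c <- integer(0)
      for (j in seq_len(nrow(cand))) {
        p <- cand$p[j]; cc <- cand$c[j]
        if (p %in% taken_p || cc %in% taken_c) next
        det$track_id[cc] <- det$track_id[p]
        taken_p <- c(taken_p, p); taken_c <- c(taken_c, cc)
      }
    }
    new <- cur[is.na(det$track_id[cur])]
    if (length(new) > 0L) {
      det$track_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
  }
  summ <- det |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(start_frame = min(.data$frame),
                     end_frame = max(.data$frame),
                     n_frames = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(termination = ifelse(.data$end_frame == max(frames),
                                       "censored-at-movie-end", "disappeared"))
  attr(det, "tracks") <- summ
  attr(det, "max_link_px") <- max_link_px
  class(det) <- c("sg_tracks", class(det))
  det
}

#' Track summary table
#'
#' @param tracks An `sg_tracks` object from [track_granules()].
#' @return The per-track summary tibble.
#' @export
track_summary <- function(tracks) {
  attr(tracks, "tracks")
}

#' Call fusion and fission events from tracks
#'
#' Fusion: at frame f, a detection whose neighbourhood (within
#' `merge_dist_px`) contains >= 2 granules from frame f-1 — the terminating
#' parents plus at most one continuing as the child — and whose area matches
#' the summed parent areas within `area_tolerance_frac`. Fission is the
#' mirror image. Disassembly events (a cell's last granule disappearing) are
#' scored separately by [score_disassembly()].
#'
#' @param tracks `sg_tracks` from [track_granules()].
#' @param merge_dist_px Association radius for event participants, pixels.
#' @param area_tolerance_frac Relative tolerance on area conservation.
#' @return Event-log tibble: `frame`, `kind` (`"fusion"`/`"fission"`),
#'   `parents`, `children` (list-columns of track ids), `row`, `col`
#'   (event location).
#' @export
call_events <- function(tracks, merge_dist_px = 10, area_tolerance_frac = 0.3) {
  det <- tracks
  summ <- track_summary(tracks)
  frames <- sort(unique(det$frame))
  events <- list()
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]; fp <- frames[fi - 1L]
    prev <- det[det$frame == fp, ]
    cur <- det[det$frame == f, ]
    if (nrow(prev) == 0L || nrow(cur) == 0L) next
    ends_prev <- summ$track_id[summ$end_frame == fp]
    starts_cur <- summ$track_id[summ$start_frame == f]
    # fusion: child at f collects terminating parents from f-1
    for (i in seq_len(nrow(cur))) {
      d <- sqrt((prev$row - cur$row[i])^2 + (prev$col - cur$col[i])^2)
      near <- d <= merge_dist_px
      is_parent <- near & (prev$track_id %in% ends_prev |
                             prev$track_id == cur$track_id[i])
      if (sum(is_parent) < 2L) next
      a_sum <- sum(prev$area_px[is_parent])
      if (abs(cur$area_px[i] - a_sum) <= area_tolerance_frac * a_sum) {
        events[[length(events) + 1L]] <- tibble(
          frame = f, kind = "fusion",
          parents = list(sort(prev$track_id[is_parent])),
          children = list(cur$track_id[i]),
          row = cur$row[i], col = cur$col[i]
        )
      }
    }
    # fission: parent at f-1 spawns starting children at f
    for (i in seq_len(nrow(prev))) {
      d <- sqrt((cur$row - prev$row[i])^2 + (cur$col - prev$col[i])^2)
      near <- d <= merge_dist_px
      is_child <- near & (cur$track_id %in% starts_cur |
                            cur$track_id == prev$track_id[i])
      if (sum(is_child) < 2L) next
      a_sum <- sum(cur$area_px[is_child])
      if (abs(a_sum - prev$area_px[i]) <= area_tolerance_frac * prev$area_px[i]) {
        events[[length(events) + 1L]] <- tibble(
          frame = f, kind = "fission",
          parents = list(prev$track_id[i]),
          children = list(sort(cur$track_id[is_child])),
          row = prev$row[i], col = prev$col[i]
        )
      }
    }
  }
  if (length(events) == 0L) {
    return(tibble(frame = integer(), kind = character(), parents = list(),
                  children = list(), row = numeric(), col = numeric()))
  }
  dplyr::bind_rows(events)
}

#' Score time to complete granule disassembly
#'
#' Complete disassembly is the first frame at which the cell contains zero
#' detections, sustained for at least `debounce_frames` consecutive frames
#' (guarding against single-frame segmentation flicker); a movie whose
#' granules persist to the end is censored at the movie length.
#'
#' @param detections Detection tibble for one cell/movie.
#' @param n_frames Total movie length in frames.
#' @param debounce_frames Minimum run of empty frames (runs truncated by
#'   the movie end still count).
#' @param frame_interval_min Minutes per frame, to express time in minutes.
#' @return One-row tibble: `time_frames`, `time_min`, `event`, `censored`.
#' @export
score_disassembly <- function(detections, n_frames, debounce_frames = 2L,
                              frame_interval_min = 1) {
  counts <- integer(n_frames)
  if (nrow(detections) > 0L) {
    tab <- table(factor(detections$frame, levels = seq_len(n_frames)))
    counts <- as.integer(tab)
  }
  empty <- counts == 0L
  t_dis <- NA_integer_
  run <- 0L
  for (f in seq_len(n_frames)) {
    if (empty[f]) {
      run <- run + 1L
      need <- min(debounce_frames, n_frames - (f - run))
      if (run >= debounce_frames || (f == n_frames && run >= need)) {
        t_dis <- f - run + 1L
        break
      }
    } else run <- 0L
  }
  event <- !is.na(t_dis)
  tf <- if (event) t_dis else n_frames
  tibble(time_frames = tf, time_min = tf * frame_interval_min,
         event = event, censored = !event)
}

#' Per-group fusion/fission prevalence
#'
#' Events per cell per unit time, summarised per group as mean +/- SEM,
#' with a two-sample Welch t statistic between each pair of groups. Both
#' prevalence conventions are emitted: the per-cell event rate and the
#' fraction of cells showing at least one event.
#'
#' @param events Tibble with one row per called event, columns `cell` and
#'   `kind` (cells with no events may be absent).
#' @param cells Tibble enumerating every analysed cell: columns `cell`,
#'   `group` (>= 2 cells per group).
#' @param duration_min Observation time per cell, minutes.
#' @return List with `rates` (tibble: `group`, `kind`, `n_cells`,
#'   `mean_rate_per_h`, `sem_rate_per_h`, `fraction_cells_with_event`) and
#'   `tests` (tibble: `kind`, `group_a`, `group_b`, `t`, `df`, `p_value`).
#' @export
event_prevalence <- function(events, cells, duration_min) {
  stopifnot_scalar_number(duration_min, "duration_min", lower = 1e-9)
  cells <- as_tibble(cells)
  if (any(table(cells$group) < 2L)) abort("each group needs >= 2 cells.")
  kinds <- c("fusion", "fission")
  per_cell <- tidyr::crossing(cells, kind = kinds) |>
    dplyr::left_join(
      events |> dplyr::count(.data$cell, .data$kind, name = "n_events"),
      by = c("cell", "kind")
    ) |>
    dplyr::mutate(n_events = tidyr::replace_na(.data$n_events, 0L),
                  rate_per_h = .data$n_events / duration_min * 60)
  rates <- per_cell |>
    dplyr::group_by(.data$group, .data$kind) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_rate_per_h = mean(.data$rate_per_h),
                     sem_rate_per_h = sem(.data$rate_per_h),
                     fraction_cells_with_event = mean(.data$n_events > 0),
                     .groups = "drop")
  groups <- sort(unique(cells$group))
  tests <- tidyr::crossing(kind = kinds,
                           tidyr::expand_grid(a = groups, b = groups)) |>
    dplyr::filter(.data$a < .data$b) |>
    purrr::pmap_dfr(function(kind, a, b) {
      xa <- per_cell$rate_per_h[per_cell$group == a & per_cell$kind == kind]
      xb <- per_cell$rate_per_h[per_cell$group == b & per_cell$kind == kind]
      tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
      if (is.null(tt)) {
        # both samples (essentially) constant: the statistic degenerates to
        # 0 for equal means, +/- Inf otherwise
        same <- isTRUE(all.equal(mean(xa), mean(xb)))
        tibble(kind = kind, group_a = a, group_b = b,
               t = if (same) 0 else sign(mean(xa) - mean(xb)) * Inf,
               df = NA_real_, p_value = if (same) 1 else 0)
      } else {
        tibble(kind = kind, group_a = a, group_b = b,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
      }
    })
  list(rates = rates, per_cell = per_cell, tests = tests)
}

#' Fraction of granule area remaining
#'
#' Total labelled granule area after a perturbation (e.g. RNase
#' microinjection) divided by the total area before it. Values near 1 mean
#' the granules resisted the perturbation; RNA-dependent granules dissolve
#' to a small fraction.
#'
#' @param pre,post `granule_labels` objects, label matrices, or scalar
#'   total areas (pixels).
#' @return Scalar fraction (>= 0; typically <= 1).
#' @examples
#' area_remaining(100, 9)
#' @export
area_remaining <- function(pre, post) {
  total <- function(x) {
    if (inherits(x, "granule_labels")) return(sum(x$labels > 0L))
    if (is.matrix(x)) return(sum(x > 0L))
    if (is.numeric(x) && length(x) == 1L) return(x)
    abort("inputs must be granule labels, label matrices, or scalar areas.")
  }
  a_pre <- total(pre); a_post <- total(post)
  if (a_pre <= 0) abort("pre-perturbation granule area is zero.")
  a_post / a_pre
}

#' Match called events against a ground-truth log
#'
#' Greedy one-to-one matching of called events to scripted truth events of
#' the same kind within a frame tolerance and spatial radius; used to score
#' event-calling precision and recall on synthetic movies.
#'
#' @param called Event log from [call_events()] (needs `frame`, `kind`,
#'   `row`, `col`).
#' @param truth Truth event log (same columns; e.g. from
#'   [render_timelapse()]'s `events` joined with locations).
#' @param frame_tol Allowed |frame difference|.
#' @param dist_tol Allowed spatial distance, pixels (ignored when either
#'   side lacks coordinates).
#' @return One-row tibble: `n_called`, `n_truth`, `n_matched`, `precision`,
#'   `recall`.
#' @export
match_events <- function(called, truth, frame_tol = 1, dist_tol = 15) {
  n_called <- nrow(called); n_truth <- nrow(truth)
  if (n_called == 0L || n_truth == 0L) {
    return(tibble(n_called = n_called, n_truth = n_truth, n_matched = 0L,
                  precision = ifelse(n_called == 0L, NA_real_, 0),
                  recall = ifelse(n_truth == 0L, NA_real_, 0)))
  }
  used <- logical(n_truth)
  matched <- 0L
  for (i in seq_len(n_called)) {
    ok <- !used & truth$kind == called$kind[i] &
      abs(truth$frame - called$frame[i]) <= frame_tol
    if (all(c("row", "col") %in% names(truth)) &&
        all(c("row", "col") %in% names(called))) {
      dd <- sqrt((truth$row - called$row[i])^2 + (truth$col - called$col[i])^2)
      ok <- ok & dd <= dist_tol
    }
    j <- which(ok)
    if (length(j) > 0L) {
      used[j[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  tibble(n_called = n_called, n_truth = n_truth, n_matched = matched,
         precision = matched / n_called, recall = matched / n_truth)
}
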