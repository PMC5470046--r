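#' Plot a FRAP fit
#'
#' Normalized recovery curve with the fitted single-exponential overlaid;
#' the dashed lines mark the fitted plateau and the first post-bleach level
#' whose gap defines the mobile fraction.
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  curve <- object$curve
  t0 <- object$curve$time_s[object$n_pre + 1L]
  fitted <- tibble(
    time_s = t0 + object$time_post_s,
    normalized = object$F0 + (object$Finf - object$F0) *
      (1 - exp(-object$k * object$time_post_s))
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_s, y = .data$normalized)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = fitted, colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$F0, object$Finf),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "time (s)", y = "normalized fluorescence",
      title = sprintf("FRAP recovery: Mf = %.2f, k = %.3g /s",
                      object$mobile_fraction, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier persistence curve
#'
#' Step curve of the fraction of cells still containing granules, with the
#' Greenwood 95% confidence band as dashed steps.
#'
#' @param object An `sg_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sg_km <- function(object, ...) {
  td <- tidy(object)
  # prepend S(0) = 1 per group so the step starts at the origin
  td <- dplyr::bind_rows(
    td |> dplyr::distinct(.data$group) |>
      dplyr::mutate(time = 0, estimate = 1, conf_low = 1, conf_high = 1),
    td
  )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dashed",
                       alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = "dashed",
                       alpha = 0.6, na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (min)", y = "fraction of cells with granules",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Costes randomization null
#'
#' Histogram of the randomized Pearson coefficients with the observed
#' coefficient marked.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coloc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$randomized_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_r, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "randomized Pearson r", y = "rounds",
      title = sprintf("observed r = %.3f, p = %.3g",
                      object$observed_r, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay granule outlines on a channel
#'
#' @param scene_or_plane An `sg_scene` or [image_plane()].
#' @param regions Optional `granule_labels` to outline.
#' @param channel Which channel of a scene to show.
#' @return A ggplot raster with granule boundaries.
#' @export
plot_granules <- function(scene_or_plane, regions = NULL,
                          channel = c("marker", "probe")) {
  channel <- match.arg(channel)
  plane <- if (inherits(scene_or_plane, "sg_scene")) {
    scene_or_plane[[channel]]
  } else scene_or_plane
  m <- as_matrix(plane)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- m[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(regions) && regions$n > 0L) {
    geo <- measure_geometry(regions)
    p <- p + ggplot2::geom_point(
      data = geo, ggplot2::aes(x = .data$col, y = .data$row),
      shape = 1, colour = "yellow",
      size = sqrt(geo$area_px / pi)
    )
  }
  p
}

#' Plot granule trajectories
#'
#' @param tracks An `sg_tracks` object.
#' @param min_length Hide tracks shorter than this many frames.
#' @return A ggplot of trajectories coloured by track.
#' @export
plot_tracks <- function(tracks, min_length = 2L) {
  keep <- track_summary(tracks) |>
    dplyr::filter(.data$n_frames >= min_length) |>
    dplyr::pull(.data$track_id)
  df <- dplyr::filter(tibble::as_tibble(tracks), .data$track_id %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   group = .data$track_id,
                                   colour = factor(.data$track_id))) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}
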