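# Ground-truthed benchmark runs: each function regenerates synthetic data
# under the package's standard study conditions, pushes it through the full
# analysis path, and reports recovery statistics. Used by the acceptance
# checks and reproducible from the command line via scripts/acceptance.R.

#' Enrichment-recovery benchmark
#'
#' Renders scenes totalling `n_scenes * granules_per_scene` granules whose
#' true probe enrichments cycle through `ratios`, runs segmentation and
#' enrichment measurement, and summarises per-class recovery plus the
#' fraction classified as enriched at `threshold`.
#'
#' @param seed Integer seed; scene seeds are derived from it.
#' @param n_scenes,granules_per_scene Benchmark size (default 25 x 40 =
#'   1,000 granules).
#' @param ratios True enrichment classes.
#' @param threshold Classification threshold.
#' @return List: `per_class` (tibble `true_ratio`, `n`, `mean_ratio`,
#'   `rel_err`), `fraction_enriched`, `design_fraction` (share of granules
#'   whose true ratio exceeds the threshold), `n_granules`.
#' @export
benchmark_enrichment <- function(seed = 1L, n_scenes = 25L,
                                 granules_per_scene = 40L,
                                 ratios = c(1, 1.2, 1.5, 2, 3),
                                 threshold = 1.4) {
  gr <- purrr::map_dfr(seq_len(n_scenes), function(i) {
    sc <- render_scene(scene_spec(
      n_granules = granules_per_scene,
      image_shape = c(320L, 320L),
      probe_enrichment_ratios = rep_len(ratios, granules_per_scene),
      seed = seed * 1000L + i
    ))
    gl <- segment_granules(sc$marker, sc$cell_mask)
    g <- measure_granules(gl, list(marker = sc$marker, probe = sc$probe))
    if (nrow(g) == 0L) return(g)
    idx <- vapply(seq_len(nrow(g)), function(k) {
      which.min((sc$truth$row - g$row[k])^2 + (sc$truth$col - g$col[k])^2)
    }, integer(1))
    g$true_ratio <- sc$truth$true_ratio[idx]
    g
  })
  per_class <- gr |>
    dplyr::filter(is.finite(.data$probe_ratio)) |>
    dplyr::group_by(true_ratio = .data$true_ratio) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_ratio = mean(.data$probe_ratio),
                     .groups = "drop") |>
    dplyr::mutate(rel_err = .data$mean_ratio / .data$true_ratio - 1)
  cls <- classify_enriched(gr, threshold = threshold)
  list(per_class = per_class,
       fraction_enriched = cls$fraction_enriched,
       design_fraction = mean(rep_len(ratios, granules_per_scene) > threshold),
       n_granules = cls$n_granules)
}

#' FRAP parameter-recovery benchmark
#'
#' Simulates `n_traces` noisy recovery curves at each true mobile fraction,
#' refits them through [frap_normalize()] + [frap_fit()], and reports
#' per-truth means plus the Spearman correlation between truth and
#' recovery.
#'
#' @param seed Integer seed.
#' @param n_traces Traces per truth value.
#' @param truths True mobile fractions.
#' @param noise_sd Trace noise, a.u. (2 = 2% of the resting level).
#' @return List: `per_truth` (tibble `true_mf`, `n`, `mean_mf`, `mean_k`),
#'   `spearman` (recovered vs true over a 5-truth x 20-replicate
#'   monotonicity grid; with fewer truth levels rank ties cap the
#'   attainable coefficient), `rate_rel_err`.
#' @export
benchmark_frap <- function(seed = 1L, n_traces = 100L,
                           truths = c(0.2, 0.6, 0.9), noise_sd = 2) {
  grid <- purrr::map_dfr(seq_along(truths), function(ti) {
    mf <- truths[ti]
    fits <- purrr::map_dfr(seq_len(n_traces), function(s) {
      tr <- simulate_frap(frap_spec(
        true_mobile_fraction = mf, true_rate_per_s = 0.1,
        noise_sd = noise_sd, post_bleach_frames = 100,
        seed = seed * 10000L + ti * 1000L + s
      ))
      f <- frap_fit(frap_normalize(tr))
      tibble(true_mf = mf, mf = f$mobile_fraction, k = f$k)
    })
    fits
  })
  per_truth <- grid |>
    dplyr::group_by(true_mf = .data$true_mf) |>
    dplyr::summarise(n = dplyr::n(), mean_mf = mean(.data$mf),
                     mean_k = mean(.data$k), .groups = "drop")
  mono <- purrr::map_dfr(seq_along(c(0.1, 0.3, 0.5, 0.7, 0.9)), function(ti) {
    mf <- c(0.1, 0.3, 0.5, 0.7, 0.9)[ti]
    purrr::map_dfr(seq_len(20L), function(s) {
      tr <- simulate_frap(frap_spec(
        true_mobile_fraction = mf, noise_sd = noise_sd,
        seed = seed * 50000L + ti * 100L + s
      ))
      tibble(true_mf = mf, mf = frap_fit(frap_normalize(tr))$mobile_fraction)
    })
  })
  list(per_truth = per_truth,
       spearman = cor(mono$true_mf, mono$mf, method = "spearman"),
       rate_rel_err = mean(per_truth$mean_k) / 0.1 - 1)
}

#' Costes type-I-error calibration benchmark
#'
#' Applies the block-randomization test to `n_reps` pairs of independent
#' noise channels and reports the rejection rate at `alpha`; a calibrated
#' test rejects at close to `alpha`.
#'
#' @param seed Integer seed.
#' @param n_reps Repetitions.
#' @param n_rounds Randomization rounds per repetition.
#' @param alpha Nominal level.
#' @param side_px Image side; blocks are 8 px (0.96 um at 0.12 um/px).
#' @return List: `rejection_rate`, `n_reps`, `mean_p`.
#' @export
benchmark_costes <- function(seed = 1L, n_reps = 500L, n_rounds = 200L,
                             alpha = 0.05, side_px = 48L) {
  roi <- matrix(TRUE, side_px, side_px)
  ps <- local_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      a <- matrix(runif(side_px^2), side_px)
      b <- matrix(runif(side_px^2), side_px)
      costes_randomization(a, b, roi, block_size_um = 0.96,
                           n_rounds = n_rounds, seed = seed * 100000L + i,
                           pixel_size_um = 0.12)$p_value
    }, numeric(1))
  })
  list(rejection_rate = mean(ps <= alpha), n_reps = n_reps, mean_p = mean(ps))
}

# build the scripted cohort of single-event movies used by the
# event-calling benchmark: alternating fusion / fission
event_cohort_scripts <- function(n_movies, seed) {
  local_seed(seed, {
    lapply(seq_len(n_movies), function(i) {
      f_event <- sample(5:8, 1)
      ctr <- c(runif(1, 45, 85), runif(1, 45, 85))
      if (i %% 2L == 0L) {
        script_fusion(12, f_event, center = ctr, radii = c(4, 4),
                      start_sep_px = 30)
      } else {
        script_fission(12, f_event, center = ctr, radii = c(4, 4),
                       end_sep_px = 30)
      }
    })
  })
}

#' Event-calling benchmark on scripted movies
#'
#' Renders a cohort of single-event movies (half fusion, half fission),
#' runs detection, tracking and event calling, and scores the called events
#' against the scripts. `what = "labels"` skips optics and noise and runs
#' on ground-truth rasters, where calling should be perfect.
#'
#' @param seed Integer seed.
#' @param n_movies Cohort size (even).
#' @param what `"rendered"` for the full imaging path, `"labels"` for
#'   truth rasters.
#' @return List: `precision`, `recall`, `n_truth`, `n_called`.
#' @export
benchmark_events <- function(seed = 1L, n_movies = 20L,
                             what = c("rendered", "labels")) {
  what <- match.arg(what)
  scripts <- event_cohort_scripts(n_movies, seed)
  scores <- purrr::imap_dfr(scripts, function(s, i) {
    sp <- scene_spec(image_shape = c(128L, 128L), seed = seed * 1000L + i)
    if (what == "labels") {
      tl <- render_timelapse(s, sp, what = "labels")
      det <- granule_detections(tl$frames)
    } else {
      tl <- render_timelapse(s, sp)
      segs <- lapply(tl$frames, function(f) segment_granules(f, tl$cell_mask))
      det <- granule_detections(segs)
    }
    trk <- track_granules(det, max_link_px = 10)
    match_events(call_events(trk), tl$events)
  })
  list(precision = sum(scores$n_matched) / sum(scores$n_called),
       recall = sum(scores$n_matched) / sum(scores$n_truth),
       n_truth = sum(scores$n_truth), n_called = sum(scores$n_called))
}

#' Survival-analysis benchmark
#'
#' Checks the Kaplan-Meier estimator at the closed-form exponential median,
#' the log-rank test's type-I error over null replicates, and its power
#' for a 4x hazard ratio at n = 50 per group.
#'
#' @param seed Integer seed.
#' @param n_null Null replicates for the type-I error.
#' @param n_power Replicates for the power estimate.
#' @return List: `surv_at_median`, `type1_rate`, `power_4x`, sizes.
#' @export
benchmark_survival <- function(seed = 1L, n_null = 1000L, n_power = 200L) {
  cohort <- sample_survival_cohort(500, 0.02, 120, seed = seed)
  s_med <- km_survival_at(kaplan_meier(cohort), log(2) / 0.02)
  null_p <- vapply(seq_len(n_null), function(i) {
    a <- sample_survival_cohort(30, 0.02, 120, "a", seed = seed * 40000L + 2L * i)
    b <- sample_survival_cohort(30, 0.02, 120, "b", seed = seed * 40000L + 2L * i + 1L)
    logrank_test(a, b)$p_value
  }, numeric(1))
  power_p <- vapply(seq_len(n_power), function(i) {
    a <- sample_survival_cohort(50, 0.04, 120, "fast", seed = seed * 90000L + 2L * i)
    b <- sample_survival_cohort(50, 0.01, 120, "slow", seed = seed * 90000L + 2L * i + 1L)
    logrank_test(a, b)$p_value
  }, numeric(1))
  list(surv_at_median = s_med,
       type1_rate = mean(null_p <= 0.05),
       power_4x = mean(power_p < 0.01),
       n_null = n_null, n_power = n_power)
}

#' RNase-sensitivity benchmark
#'
#' Renders paired pre/post-injection scenes at a target area-remaining
#' fraction and measures the fraction through segmentation, emulating the
#' RNase-resistance readout that separates aberrant from liquid-like
#' granules.
#'
#' @param seed Integer seed.
#' @param target_frac Scripted fraction of granule area remaining.
#' @return List: `measured_frac`, `target_frac`.
#' @export
benchmark_rnase <- function(seed = 1L, target_frac = 0.88) {
  pair <- render_rnase_pair(
    scene_spec(n_granules = 8, granule_radius_px = c(6, 0.5),
               seed = seed * 17L + 3L),
    area_remaining_frac = target_frac
  )
  seg_pre <- segment_granules(pair$pre$marker, pair$pre$cell_mask)
  seg_post <- segment_granules(pair$post$marker, pair$post$cell_mask)
  list(measured_frac = area_remaining(seg_pre, seg_post),
       target_frac = target_frac)
}
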