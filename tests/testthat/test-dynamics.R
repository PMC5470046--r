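test_that("a static scene yields one full-length zero-displacement track per granule", {
  st <- script_static(6, tibble::tibble(id = 1:3, row = c(40, 70, 90),
                                        col = c(40, 80, 50), radius_px = 4))
  res <- track_script(st)
  summ <- track_summary(res$tracks)
  expect_equal(nrow(summ), 3L)
  expect_true(all(summ$start_frame == 1L & summ$end_frame == 6L))
  disp <- res$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(d = max(row) - min(row) + max(col) - min(col))
  expect_true(all(disp$d == 0))
  expect_true(all(summ$termination == "censored-at-movie-end"))
})

test_that("scripted drift is recovered within 1 px RMS", {
  dr <- script_drift(12, tibble::tibble(id = 1:2, row = c(45, 85),
                                        col = c(30, 30), radius_px = c(4, 5)),
                     velocity = c(0, 2))
  res <- track_script(dr)
  joined <- dplyr::inner_join(
    tibble::as_tibble(res$tracks), res$timelapse$detections,
    by = "frame", suffix = c("_meas", "_true"),
    relationship = "many-to-many"
  ) |>
    dplyr::group_by(frame, track_id) |>
    dplyr::slice_min(abs(row_meas - row_true) + abs(col_meas - col_true),
                     n = 1) |>
    dplyr::ungroup()
  rms <- sqrt(mean((joined$row_meas - joined$row_true)^2 +
                     (joined$col_meas - joined$col_true)^2))
  expect_lt(rms, 1)
  expect_equal(nrow(track_summary(res$tracks)), 2L)
})

test_that("tracking is invariant to detection ordering within a frame", {
  dr <- script_drift(8, tibble::tibble(id = 1:3, row = c(40, 70, 95),
                                       col = c(40, 60, 80), radius_px = 4),
                     velocity = c(1, 1))
  tl <- render_timelapse(dr, scene_spec(image_shape = c(128L, 128L)),
                         what = "labels")
  det <- granule_detections(tl$frames)
  set.seed(42)
  shuffled <- det[sample(nrow(det)), ]
  t1 <- track_granules(det, max_link_px = 6)
  t2 <- track_granules(shuffled, max_link_px = 6)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(t1), frame, row, col)$track_id,
    dplyr::arrange(tibble::as_tibble(t2), frame, row, col)$track_id
  )
})

test_that("displacement beyond max_link terminates tracks and starts new ones", {
  # both granules jump to fresh positions far from every frame-3 detection
  wp <- dplyr::bind_rows(
    tidyr::crossing(frame = 1:3,
                    tibble::tibble(id = 1:2, row = c(40, 90),
                                   col = c(40, 90), radius_px = 4)),
    tidyr::crossing(frame = 4:6,
                    tibble::tibble(id = 1:2, row = c(60, 105),
                                   col = c(100, 30), radius_px = 4))
  )
  res <- track_script(timelapse_script(wp), max_link_px = 5)
  summ <- track_summary(res$tracks)
  expect_equal(nrow(summ), 4L)
  expect_equal(sum(summ$termination == "disappeared"), 2L)
})

test_that("scripted fusion and fission are each called once at the right frame", {
  fu <- track_script(script_fusion(12, 8, center = c(64, 64), radii = c(4, 4)))
  expect_equal(nrow(fu$events), 1L)
  expect_equal(fu$events$kind, "fusion")
  expect_lte(abs(fu$events$frame - 8L), 1L)
  expect_length(fu$events$parents[[1]], 2L)

  fi <- track_script(script_fission(12, 6, center = c(64, 64), radii = c(4, 4)))
  expect_equal(nrow(fi$events), 1L)
  expect_equal(fi$events$kind, "fission")
  expect_lte(abs(fi$events$frame - 6L), 1L)
  expect_length(fi$events$children[[1]], 2L)
})

test_that("a movie without events produces an empty log", {
  st <- script_static(5, tibble::tibble(id = 1:2, row = c(40, 80),
                                        col = c(40, 80), radius_px = 4))
  res <- track_script(st)
  expect_equal(nrow(res$events), 0L)
})

test_that("event calling on truth rasters has perfect precision and recall", {
  scripts <- c(
    lapply(1:3, function(i) script_fusion(12, 5 + i, center = c(50 + 8 * i, 60),
                                          radii = c(4, 4))),
    lapply(1:3, function(i) script_fission(12, 4 + i, center = c(40 + 8 * i, 70),
                                           radii = c(4, 4)))
  )
  scores <- purrr::map_dfr(scripts, function(s) {
    res <- track_script(s)
    match_events(res$events, res$timelapse$events)
  })
  expect_equal(sum(scores$n_matched), 6L)
  expect_true(all(scores$precision == 1))
  expect_true(all(scores$recall == 1))
})

test_that("event prevalence contracts: identical groups, zero cells, single-cell SEM", {
  events <- tibble::tibble(cell = c(1, 1, 2, 3, 4), kind = "fusion")
  cells <- tibble::tibble(cell = 1:6, group = rep(c("a", "b"), each = 3))
  pv <- event_prevalence(events, cells, duration_min = 120)
  expect_equal(nrow(pv$rates), 4L) # 2 groups x {fusion, fission}
  fus <- dplyr::filter(pv$rates, kind == "fusion")
  expect_equal(fus$mean_rate_per_h[fus$group == "a"], mean(c(2, 1, 1)) / 2)
  # identical groups: t ~ 0
  same <- event_prevalence(
    tibble::tibble(cell = c(1, 4), kind = "fusion"),
    tibble::tibble(cell = 1:6, group = rep(c("a", "b"), each = 3)), 60
  )
  expect_equal(same$tests$t[same$tests$kind == "fusion"], 0, tolerance = 1e-9)
  expect_error(
    event_prevalence(events, tibble::tibble(cell = 1, group = "a"), 60),
    ">= 2 cells"
  )
})

test_that("scripted event rates are recovered at the cohort level", {
  # group A: 2 fusions/h per cell scripted; group B: none
  movies_a <- lapply(1:4, function(i) {
    track_script(script_fusion(12, 6 + (i %% 3), center = c(64, 64),
                               radii = c(4, 4)))$events |>
      dplyr::mutate(cell = i)
  })
  cells <- tibble::tibble(cell = 1:8, group = rep(c("a", "b"), each = 4))
  pv <- event_prevalence(dplyr::bind_rows(movies_a), cells,
                         duration_min = 30) # 12 frames @ 2.5 min
  fus <- dplyr::filter(pv$rates, kind == "fusion")
  expect_equal(fus$mean_rate_per_h[fus$group == "a"], 2)
  expect_equal(fus$mean_rate_per_h[fus$group == "b"], 0)
  expect_lt(pv$tests$p_value[pv$tests$kind == "fusion"], 0.01)
})

test_that("area_remaining is exact on arithmetic cases and errors on empty pre", {
  expect_equal(area_remaining(100, 100), 1)
  expect_equal(area_remaining(100, 9), 0.09)
  lab_pre <- matrix(0L, 20, 20); lab_pre[5:8, 5:8] <- 1L
  lab_post <- matrix(0L, 20, 20); lab_post[5:6, 5:6] <- 1L
  expect_equal(area_remaining(lab_pre, lab_post), 0.25)
  expect_error(area_remaining(matrix(0L, 20, 20), lab_post), "zero")
})

test_that("rendered RNase pairs measure near the scripted area fraction", {
  pair <- render_rnase_pair(scene_spec(n_granules = 8, seed = 55,
                                       granule_radius_px = c(6, 0.5)),
                            area_remaining_frac = 0.88)
  seg_pre <- segment_granules(pair$pre$marker, pair$pre$cell_mask)
  seg_post <- segment_granules(pair$post$marker, pair$post$cell_mask)
  frac <- area_remaining(seg_pre, seg_post)
  expect_gt(frac, 0.83)
  expect_lt(frac, 0.93)
})

test_that("disassembly scoring debounces single-frame dropouts and censors persistence", {
  det <- tibble::tibble(frame = c(1, 2, 3, 5), det = 1, row = 50, col = 50,
                        area_px = 50)
  # frame 4 empty but granules return at 5: not disassembly; empty 6..10 is
  sc <- score_disassembly(det, n_frames = 10)
  expect_true(sc$event)
  expect_equal(sc$time_frames, 6)

  persistent <- tibble::tibble(frame = 1:10, det = 1, row = 50, col = 50,
                               area_px = 50)
  sc2 <- score_disassembly(persistent, n_frames = 10)
  expect_false(sc2$event)
  expect_equal(sc2$time_frames, 10)
})

test_that("disassembly is scored end-to-end from a scripted movie", {
  ds <- script_disassembly(10, 7, tibble::tibble(id = 1:2, row = c(50, 80),
                                                 col = c(50, 80),
                                                 radius_px = 4))
  tl <- render_timelapse(ds, scene_spec(image_shape = c(128L, 128L)),
                         what = "labels")
  det <- granule_detections(tl$frames)
  sc <- score_disassembly(det, n_frames = 10, frame_interval_min = 2)
  expect_true(sc$event)
  expect_equal(sc$time_frames, 7)
  expect_equal(sc$time_min, 14)
})
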