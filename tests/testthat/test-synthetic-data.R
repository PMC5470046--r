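test_that("empty scene renders cytoplasm + background everywhere in the cell", {
  sp <- scene_spec(n_granules = 0, noise = FALSE, psf_sigma_px = 0,
                   background_offset = 10, seed = 1)
  sc <- render_scene(sp)
  expect_equal(nrow(sc$truth), 0L)
  inside <- as.numeric(sc$probe)[sc$cell_mask]
  expect_true(all(inside == sp$probe_cytoplasm_level + sp$background_offset))
  outside <- as.numeric(sc$probe)[!sc$cell_mask]
  expect_true(all(outside == sp$background_offset))
})

test_that("noiseless unblurred granule is exactly ratio x cytoplasm inside the disk", {
  sp <- scene_spec(n_granules = 1, probe_enrichment_ratios = 3,
                   psf_sigma_px = 0, noise = FALSE, background_offset = 0,
                   seed = 11)
  sc <- render_scene(sp)
  d <- (row(sc$probe_ideal) - sc$truth$row[1])^2 +
    (col(sc$probe_ideal) - sc$truth$col[1])^2 <= sc$truth$radius_px[1]^2
  expect_equal(unique(as.numeric(sc$probe)[d]), 3 * sp$probe_cytoplasm_level)
  expect_equal(unique(round(as.numeric(sc$probe)[sc$cell_mask & !d], 9)),
               sp$probe_cytoplasm_level)
})

test_that("PSF-blurred noisy granules hit the specified ratio by direct disk averaging", {
  sp <- scene_spec(n_granules = 4, probe_enrichment_ratios = 3,
                   granule_radius_px = c(6, 0), psf_sigma_px = 1.5,
                   background_offset = 0, seed = 42)
  sc <- render_scene(sp)
  far <- sc$cell_mask
  for (i in seq_len(nrow(sc$truth))) {
    far <- far & ((row(far) - sc$truth$row[i])^2 +
                    (col(far) - sc$truth$col[i])^2 > (sc$truth$radius_px[i] + 12)^2)
  }
  probe <- as.numeric(sc$probe)
  dim(probe) <- dim(sc$probe)
  for (i in seq_len(nrow(sc$truth))) {
    d <- (row(probe) - sc$truth$row[i])^2 +
      (col(probe) - sc$truth$col[i])^2 <= sc$truth$radius_px[i]^2
    # offset-corrected disk mean over far-field mean (oracle measurement)
    r_meas <- (mean(probe[d]) - sp$background_offset) /
      (mean(probe[far]) - sp$background_offset)
    expect_gt(r_meas, 2.7)
    expect_lt(r_meas, 3.3)
  }
})

test_that("identical (spec, seed) pairs render bit-identical scenes", {
  sp <- scene_spec(n_granules = 6, probe_enrichment_ratios = c(1, 2), seed = 9)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(as.numeric(a$marker), as.numeric(b$marker))
  expect_identical(as.numeric(a$probe), as.numeric(b$probe))
  expect_identical(a$truth, b$truth)
  c <- render_scene(scene_spec(n_granules = 6,
                               probe_enrichment_ratios = c(1, 2), seed = 10))
  expect_false(identical(as.numeric(a$marker), as.numeric(c$marker)))
})

test_that("total noiseless marker intensity is invariant under granule repositioning", {
  # invariance holds up to disk digitisation: a disk at fractional centre
  # covers a few pixels more or fewer, so compare at the per-mille level
  totals <- vapply(c(3, 4, 5), function(s) {
    sc <- render_scene(scene_spec(n_granules = 5, granule_radius_px = c(5, 0),
                                  noise = FALSE, background_offset = 0,
                                  psf_sigma_px = 1, seed = s))
    sum(sc$marker_ideal)
  }, numeric(1))
  expect_lt((max(totals) - min(totals)) / mean(totals), 2e-3)
})

test_that("impossible granule packing raises a placement error", {
  expect_error(
    render_scene(scene_spec(image_shape = c(64L, 64L), n_granules = 200,
                            granule_radius_px = c(5, 0), seed = 1)),
    class = "sgquant_placement_error"
  )
})

test_that("immobile noiseless FRAP trace is flat at (1 - depth) x L(t) x pre-level", {
  sp <- frap_spec(true_mobile_fraction = 0, noise_sd = 0, bleach_depth = 0.8,
                  acquisition_loss_per_frame = 0.01, background_level = 0,
                  pre_bleach_frames = 3, post_bleach_frames = 20)
  tr <- simulate_frap(sp)
  frame <- seq_len(nrow(tr)) - 1
  L <- (1 - 0.01)^frame
  post <- frame >= 3
  expect_equal(tr$roi[post], (1 - 0.8) * L[post] * sp$pre_level)
  expect_equal(tr$roi[!post], L[!post] * sp$pre_level)
})

test_that("FRAP closed form: full bleach, Mf 0.5, k 0.1 gives 0.5(1-e^-1)P at t' = 10 s", {
  sp <- frap_spec(pre_bleach_frames = 2, post_bleach_frames = 30,
                  frame_interval_s = 1, bleach_depth = 1,
                  true_mobile_fraction = 0.5, true_rate_per_s = 0.1,
                  acquisition_loss_per_frame = 0, noise_sd = 0,
                  background_level = 0)
  tr <- simulate_frap(sp)
  # first post-bleach frame is index n_pre + 1; t' = 10 s is 10 frames later
  expect_equal(tr$roi[2 + 1 + 10], 0.5 * (1 - exp(-1)) * sp$pre_level)
})

test_that("noiseless FRAP trace matches the generating closed form to machine precision", {
  sp <- frap_spec(true_mobile_fraction = 0.7, true_rate_per_s = 0.15,
                  bleach_depth = 0.9, acquisition_loss_per_frame = 0.005,
                  noise_sd = 0)
  tr <- simulate_frap(sp)
  f <- seq_len(nrow(tr)) - 1
  L <- (1 - sp$acquisition_loss_per_frame)^f
  tp <- pmax(0, tr$time_s - tr$time_s[sp$pre_bleach_frames + 1])
  expected <- ifelse(
    f >= sp$pre_bleach_frames,
    L * sp$pre_level * (1 - sp$bleach_depth +
                          sp$bleach_depth * 0.7 * (1 - exp(-0.15 * tp))),
    L * sp$pre_level
  ) + sp$background_level
  expect_equal(tr$roi, expected, tolerance = 1e-12)
})

test_that("timelapse script validation enforces event participants and area conservation", {
  wp <- tidyr::crossing(frame = 1:5,
                        tibble::tibble(id = 1L, row = 50, col = 50,
                                       radius_px = 4))
  bad_parent <- tibble::tibble(frame = 3L, kind = "fusion",
                               parents = list(c(1L, 9L)), children = list(1L))
  expect_error(timelapse_script(wp, bad_parent), "parents missing")

  fs <- script_fusion(10, 6, center = c(60, 60), radii = c(4, 4))
  child_r <- fs$waypoints$radius_px[fs$waypoints$id == 3L][1]
  expect_equal(child_r^2, 4^2 + 4^2) # area conservation by construction

  wp_bad <- fs$waypoints
  wp_bad$radius_px[wp_bad$id == 3L] <- 2
  expect_error(timelapse_script(wp_bad, fs$events), "area deviates")
})

test_that("a scripted fusion drops the rendered granule count by one at the event frame", {
  fs <- script_fusion(12, 8, center = c(64, 64), radii = c(4, 4))
  tl <- render_timelapse(fs, scene_spec(image_shape = c(128L, 128L)),
                         what = "labels")
  counts <- vapply(tl$frames, function(m) length(unique(m[m > 0])), integer(1))
  expect_equal(counts[7], 2L)
  expect_equal(counts[8], 1L)
  expect_equal(tl$events$kind, "fusion")
  expect_equal(tl$events$frame, 8L)
})

test_that("a static no-event movie renders identical noiseless frames", {
  st <- script_static(4, tibble::tibble(id = 1:2, row = c(50, 70),
                                        col = c(50, 70), radius_px = 4))
  tl <- render_timelapse(st, scene_spec(image_shape = c(128L, 128L),
                                        noise = FALSE))
  expect_equal(nrow(tl$events), 0L)
  for (f in 2:4) {
    expect_equal(as.numeric(tl$frames[[f]]), as.numeric(tl$frames[[1]]))
  }
})

test_that("survival cohort sampling respects hazard limits and the exponential median", {
  fast <- sample_survival_cohort(50, hazard_per_min = 1e6, censor_at_min = 120,
                                 seed = 1)
  expect_true(all(fast$event))
  expect_lt(max(fast$time_min), 1e-3)

  allcens <- sample_survival_cohort(20, 0.02, censor_at_min = 0, seed = 2)
  expect_true(all(allcens$censored))

  big <- sample_survival_cohort(500, 0.02, censor_at_min = 120, seed = 3)
  med <- median(big$time_min) # censoring at 120 barely touches the median
  expect_equal(med, log(2) / 0.02, tolerance = 0.1)
})
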