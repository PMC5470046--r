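test_that("uniform plane gives enrichment ratio exactly 1", {
  fx <- disk_fixture(inside = 100, outside = 100)
  r <- enrichment_ratio(fx$regions, fx$img, 1L, background = NULL)
  expect_equal(r$ratio, 1)
  expect_true(r$measurable)
})

test_that("noiseless disk at 300 over 100 cytoplasm gives ratio exactly 3", {
  fx <- disk_fixture(inside = 300, outside = 100)
  r <- enrichment_ratio(fx$regions, fx$img, 1L, background = 0)
  expect_equal(r$ratio, 3)
})

test_that("surround excludes neighbouring granules and empty surrounds flag unmeasurable", {
  # two disks 6 px apart: granule 2 sits inside granule 1's annulus and must
  # be excluded from its surround
  n <- 64
  img <- matrix(100, n, n)
  labels <- matrix(0L, n, n)
  d1 <- (row(img) - 32)^2 + (col(img) - 25)^2 <= 16
  d2 <- (row(img) - 32)^2 + (col(img) - 40)^2 <= 16
  img[d1] <- 300; img[d2] <- 900
  labels[d1] <- 1L; labels[d2] <- 2L
  regions <- structure(list(labels = labels, cell_mask = matrix(TRUE, n, n),
                            n = 2L), class = "granule_labels")
  r1 <- enrichment_ratio(regions, image_plane(img), 1L, background = 0,
                         surround_gap_px = 2, surround_width_px = 12)
  expect_equal(r1$ratio, 3) # untouched by the 900-level neighbour

  # cell mask so tight the annulus is empty -> unmeasurable, no error
  tight <- structure(list(labels = labels, cell_mask = d1, n = 2L),
                     class = "granule_labels")
  r_tight <- enrichment_ratio(tight, image_plane(img), 1L, background = 0)
  expect_false(r_tight$measurable)
  expect_true(is.na(r_tight$ratio))
})

test_that("rendered scenes recover true ratios within 10% per class", {
  gr <- measure_scene(render_scene(scene_spec(
    n_granules = 24, image_shape = c(320L, 320L),
    probe_enrichment_ratios = rep(c(1, 1.5, 3), 8), seed = 31
  )))
  by_class <- tapply(gr$probe_ratio / gr$true_ratio, gr$true_ratio, mean)
  expect_true(all(abs(by_class - 1) < 0.1))
})

test_that("classification uses a strict inequality at the threshold", {
  tbl <- tibble::tibble(probe_ratio = c(1.39, 1.40, 1.41))
  cs <- classify_enriched(tbl, threshold = 1.4)
  expect_equal(cs$n_enriched, 1L)
  expect_equal(cs$n_granules, 3L)
  cs0 <- classify_enriched(tbl, threshold = 0)
  expect_equal(cs0$fraction_enriched, 1)
})

test_that("fraction enriched is non-increasing in the threshold", {
  set.seed(5)
  tbl <- tibble::tibble(probe_ratio = exp(rnorm(500, 0.2, 0.4)))
  taus <- seq(0.5, 3, by = 0.25)
  fr <- vapply(taus, function(t) {
    classify_enriched(tbl, threshold = t)$fraction_enriched
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("classification on an empty table returns an empty summary", {
  cs <- classify_enriched(tibble::tibble(probe_ratio = numeric()))
  expect_equal(cs$n_granules, 0L)
  expect_true(is.na(cs$fraction_enriched))
})

test_that("a mixed population's enriched fraction matches its design fraction", {
  # 10% of granules at true ratio 3, 90% at 1; tau = 1.4 separates the
  # classes cleanly at the generator's noise level
  ratios <- rep(c(3, 1, 1, 1, 1, 1, 1, 1, 1, 1), 3)
  gr <- purrr::map_dfr(1:3, function(s) {
    measure_scene(render_scene(scene_spec(
      n_granules = 30, image_shape = c(360L, 360L),
      probe_enrichment_ratios = ratios, seed = 400 + s
    )))
  })
  cs <- classify_enriched(gr, threshold = 1.4)
  expect_equal(cs$fraction_enriched, 0.1, tolerance = 0.3) # +/- 3 points
})

test_that("gain invariance: scaling a channel leaves ratios, classes and r unchanged", {
  sc <- render_scene(scene_spec(n_granules = 10, seed = 77,
                                probe_enrichment_ratios = c(1, 2, 3)))
  gl <- segment_granules(sc$marker, sc$cell_mask)
  base <- measure_granules(gl, list(marker = sc$marker, probe = sc$probe))
  scaled <- measure_granules(gl, list(
    marker = sc$marker,
    probe = image_plane(as_matrix_for_test(sc$probe) * 10, channel = "probe")
  ))
  expect_equal(scaled$probe_ratio, base$probe_ratio, tolerance = 1e-10)
  expect_identical(
    classify_enriched(scaled, 1.4)$n_enriched,
    classify_enriched(base, 1.4)$n_enriched
  )
  expect_equal(enrichment_correlation(scaled)$r,
               enrichment_correlation(base)$r, tolerance = 1e-10)
})

test_that("offset without background correction biases R toward 1; subtraction restores it", {
  fx <- disk_fixture(inside = 300, outside = 100)
  shifted <- image_plane(as_matrix_for_test(fx$img) + 200)
  r_naive <- enrichment_ratio(fx$regions, shifted, 1L, background = NULL)
  expect_lt(r_naive$ratio, 3)
  expect_gt(r_naive$ratio, 1)
  r_corr <- enrichment_ratio(fx$regions, shifted, 1L, background = 200)
  expect_equal(r_corr$ratio, 3)
})

test_that("enrichment correlation handles exact and degenerate cases", {
  tbl <- tibble::tibble(marker_ratio = c(1, 2, 3, 4),
                        probe_ratio = c(2, 4, 6, 8))
  expect_equal(enrichment_correlation(tbl)$r, 1)
  tbl2 <- tibble::tibble(marker_ratio = c(1, 2, 1.5),
                         probe_ratio = c(2, 1, 1.5))
  expect_equal(enrichment_correlation(tbl2)$r, -1)
  degen <- tibble::tibble(marker_ratio = c(1, 1, 1), probe_ratio = c(1, 2, 3))
  expect_warning(res <- enrichment_correlation(degen), "zero variance")
  expect_true(is.na(res$r))
})

test_that("correlation of log-normal ratio pairs is recovered at n = 1000", {
  set.seed(8)
  z1 <- rnorm(1000); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(1000)
  tbl <- tibble::tibble(marker_ratio = exp(0.3 * z1 + 0.2),
                        probe_ratio = exp(0.3 * z2 + 0.2))
  target <- cor(tbl$marker_ratio, tbl$probe_ratio) # sampling oracle
  expect_equal(enrichment_correlation(tbl)$r, target, tolerance = 1e-12)
  expect_equal(target, 0.6, tolerance = 0.07)
})

test_that("timecourse fractions are monotone for drifting ratios and SEM absent for one replicate", {
  set.seed(3)
  tbl <- purrr::map_dfr(1:5, function(tp) {
    mu <- 1 + (tp - 1) * 0.5 # 1.0 -> 3.0 across 5 time points
    tibble::tibble(time = tp, replicate = rep(1:3, each = 40),
                   probe_ratio = pmax(0.1, rnorm(120, mu, 0.05)))
  })
  tc <- timecourse_fraction(tbl, threshold = 1.5, replicate_col = "replicate")
  expect_true(all(diff(tc$fraction_enriched) >= 0))
  expect_true(all(is.finite(tc$sem)))

  single <- timecourse_fraction(dplyr::filter(tbl, replicate == 1),
                                threshold = 1.5)
  expect_true(all(is.na(single$sem)))

  low <- timecourse_fraction(
    tibble::tibble(time = rep(1:3, each = 10), probe_ratio = 1),
    threshold = 1.5
  )
  expect_true(all(low$fraction_enriched == 0))
})
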