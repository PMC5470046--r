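test_that("double normalization: halved flat ROI gives F = 1 pre, 0.5 post", {
  tr <- tibble::tibble(
    time_s = 0:9,
    roi = c(rep(100, 3), rep(50, 7)),
    reference = 100,
    background = 0
  )
  nn <- frap_normalize(tr, n_pre = 3)
  expect_equal(nn$normalized[1:3], rep(1, 3))
  expect_equal(nn$normalized[4:10], rep(0.5, 7))
})

test_that("double normalization cancels pure acquisition loss exactly", {
  sp <- frap_spec(true_mobile_fraction = 0, bleach_depth = 0,
                  acquisition_loss_per_frame = 0.01, noise_sd = 0,
                  background_level = 0)
  nn <- frap_normalize(simulate_frap(sp))
  expect_equal(nn$normalized, rep(1, nrow(nn)), tolerance = 1e-12)
})

test_that("normalization errors name the frame where reference falls to background", {
  tr <- tibble::tibble(time_s = 0:5, roi = 100,
                       reference = c(100, 100, 100, 5, 100, 100),
                       background = 10)
  expect_error(frap_normalize(tr, n_pre = 2), "frame 4")
})

test_that("normalized curves from the generator track the recovery formula", {
  sp <- frap_spec(true_mobile_fraction = 0.6, true_rate_per_s = 0.1,
                  noise_sd = 2, post_bleach_frames = 100, seed = 6)
  nn <- frap_normalize(simulate_frap(sp))
  post <- (sp$pre_bleach_frames + 1):nrow(nn)
  tp <- nn$time_s[post] - nn$time_s[post[1]]
  expected <- (1 - sp$bleach_depth) +
    sp$bleach_depth * 0.6 * (1 - exp(-0.1 * tp))
  rms <- sqrt(mean((nn$normalized[post] - expected)^2))
  expect_lt(rms, 0.03)
})

test_that("closed-form fits: F0 0.2 / Finf 0.7 gives Mf 0.625; flat curve gives 0", {
  tp <- 0:40
  curve <- tibble::tibble(
    time_s = c(-2, -1, tp),
    normalized = c(1, 1, 0.2 + 0.5 * (1 - exp(-0.2 * tp)))
  )
  fit <- frap_fit(curve, n_pre = 2)
  expect_equal(fit$mobile_fraction, 0.625, tolerance = 1e-6)
  expect_equal(fit$k, 0.2, tolerance = 1e-6)
  expect_true(fit$converged)

  flat <- tibble::tibble(time_s = c(-1, 0:10),
                         normalized = c(1, rep(0.3, 11)))
  ff <- frap_fit(flat, n_pre = 1)
  expect_equal(ff$mobile_fraction, 0)
  expect_equal(ff$k, 0)
})

test_that("tidy and glance expose the fitted parameters", {
  tr <- simulate_frap(frap_spec(seed = 2))
  fit <- frap_fit(frap_normalize(tr))
  td <- tidy(fit)
  expect_setequal(td$term, c("F0", "Finf", "k", "mobile_fraction"))
  gl <- glance(fit)
  expect_true(all(c("mobile_fraction", "k", "sse", "converged") %in% names(gl)))
  expect_equal(td$estimate[td$term == "mobile_fraction"], gl$mobile_fraction)
})

test_that("mobile fractions are recovered from noisy traces", {
  fits <- lapply(1:25, function(s) {
    frap_fit(frap_normalize(simulate_frap(
      frap_spec(true_mobile_fraction = 0.6, noise_sd = 2,
                post_bleach_frames = 100, seed = 500 + s)
    )))
  })
  mfs <- vapply(fits, function(f) f$mobile_fraction, numeric(1))
  expect_equal(mean(mfs), 0.6, tolerance = 0.05)
  ks <- vapply(fits, function(f) f$k, numeric(1))
  expect_equal(mean(ks), 0.1, tolerance = 0.02)
})

test_that("normalization and the fit are invariant to a common gain", {
  tr <- simulate_frap(frap_spec(seed = 4))
  scaled <- tr
  scaled$roi <- tr$roi * 7
  scaled$reference <- tr$reference * 7
  scaled$background <- tr$background * 7
  attr(scaled, "n_pre") <- attr(tr, "n_pre")
  f1 <- frap_fit(frap_normalize(tr))
  f2 <- frap_fit(frap_normalize(scaled))
  expect_equal(f1$mobile_fraction, f2$mobile_fraction, tolerance = 1e-8)
  expect_equal(f1$k, f2$k, tolerance = 1e-8)
})

test_that("recovered mobile fraction is monotone in the truth", {
  truths <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  grid <- purrr::map_dfr(truths, function(mf) {
    mfs <- vapply(1:8, function(s) {
      frap_fit(frap_normalize(simulate_frap(
        frap_spec(true_mobile_fraction = mf, noise_sd = 2,
                  seed = round(1000 * mf) + s)
      )))$mobile_fraction
    }, numeric(1))
    tibble::tibble(truth = mf, recovered = mfs)
  })
  rho <- cor(grid$truth, grid$recovered, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("aggregation pools curves and mobile fractions with SEM contracts", {
  tr <- simulate_frap(frap_spec(seed = 9))
  fit <- frap_fit(frap_normalize(tr))
  two <- aggregate_frap(list(fit, fit))
  expect_equal(unique(two$curve$sem), 0)
  expect_equal(two$mobile_fraction$sem_mf, 0)

  one <- aggregate_frap(list(fit))
  expect_true(is.na(one$mobile_fraction$sem_mf))
  expect_equal(one$mobile_fraction$mean_mf, fit$mobile_fraction)

  high <- lapply(1:10, function(s) frap_fit(frap_normalize(simulate_frap(
    frap_spec(true_mobile_fraction = 0.8, noise_sd = 2, seed = 2000 + s)))))
  low <- lapply(1:10, function(s) frap_fit(frap_normalize(simulate_frap(
    frap_spec(true_mobile_fraction = 0.2, noise_sd = 2, seed = 3000 + s)))))
  agg <- aggregate_frap(list(mobile = high, immobile = low))
  mf <- agg$mobile_fraction
  gap <- abs(diff(mf$mean_mf))
  pooled <- sqrt(sum(mf$sem_mf^2))
  expect_gt(gap, 5 * pooled)
})

test_that("two-channel protocol dissociates a mobile marker from an immobile probe", {
  marker_fit <- frap_fit(frap_normalize(simulate_frap(
    frap_spec(true_mobile_fraction = 0.8, noise_sd = 2, seed = 11)
  )))
  probe_fit <- frap_fit(frap_normalize(simulate_frap(
    frap_spec(true_mobile_fraction = 0, noise_sd = 2, seed = 12)
  )))
  expect_gte(marker_fit$mobile_fraction - probe_fit$mobile_fraction, 0.5)
})
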