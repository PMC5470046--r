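#' Double-normalize a FRAP trace
#'
#' Corrects a raw bleach-ROI time course for whole-field acquisition
#' bleaching and for starting intensity. With background-subtracted signals,
#' \deqn{F(t) = \frac{\overline{ref}_{pre}}{ref(t)} \cdot
#'             \frac{roi(t)}{\overline{roi}_{pre}}}
#' so the pre-bleach mean of \eqn{F} is ~1 and a trace whose ROI and
#' reference decay identically (pure acquisition loss) normalises to
#' \eqn{F \equiv 1}. \eqn{F(t)} is invariant to rescaling all three traces
#' by a common positive gain.
#'
#' @param trace Tibble with columns `time_s`, `roi`, `reference`,
#'   `background` (e.g. from [simulate_frap()] or [read_frap_traces()]).
#' @param n_pre Number of pre-bleach frames; taken from the trace's `n_pre`
#'   attribute when `NULL`.
#' @return The trace with a `normalized` column appended, class
#'   `frap_trace`, `n_pre` attribute set.
#' @export
frap_normalize <- function(trace, n_pre = NULL) {
  n_pre <- n_pre %||% attr(trace, "n_pre")
  if (is.null(n_pre) || n_pre < 1L) {
    abort("`n_pre` (pre-bleach frame count) must be >= 1.")
  }
  need <- c("time_s", "roi", "reference", "background")
  if (!all(need %in% names(trace))) {
    abort(paste("trace needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(trace) <= n_pre) abort("trace has no post-bleach frames.")
  roi <- trace$roi - trace$background
  ref <- trace$reference - trace$background
  bad <- which(ref <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "reference - background is <= 0 at frame %d; cannot normalize.", bad[1]
    ))
  }
  pre <- seq_len(n_pre)
  if (mean(roi[pre]) <= 0) {
    abort("pre-bleach ROI does not exceed background; cannot normalize.")
  }
  out <- trace
  out$normalized <- (mean(ref[pre]) / ref) * (roi / mean(roi[pre]))
  attr(out, "n_pre") <- as.integer(n_pre)
  if (!inherits(out, "frap_trace")) class(out) <- c("frap_trace", class(out))
  out
}

#' Fit single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of \eqn{F(t') = F_0 + (F_\infty - F_0)(1 - e^{-k t'})}
#' to the post-bleach frames, with \eqn{t' = 0} at the first post-bleach
#' frame. The mobile fraction is
#' \eqn{M_f = (F_\infty - F_0)/(1 - F_0)}: the recovered share of the
#' bleached signal. The reported `mobile_fraction` is clipped to
#' \[0, 1.05\] (`mobile_fraction_raw` keeps the unclipped value).
#'
#' Initialisation is deterministic: \eqn{F_0} = first post-bleach point,
#' \eqn{F_\infty} = mean of the last 3 points, \eqn{k} = ln 2 over the time
#' to half recovery, with \eqn{k} bounded positive.
#'
#' @param trace A normalized trace from [frap_normalize()], or any tibble
#'   with `time_s` and `normalized` columns plus an `n_pre` attribute (or
#'   the `n_pre` argument).
#' @param n_pre Pre-bleach frame count override.
#' @return A `frap_fit` object; see [tidy.frap_fit()] / [glance.frap_fit()].
#' @examples
#' tr <- simulate_frap(frap_spec(true_mobile_fraction = 0.6, seed = 3))
#' fit <- frap_fit(frap_normalize(tr))
#' glance(fit)
#' @export
frap_fit <- function(trace, n_pre = NULL) {
  n_pre <- n_pre %||% attr(trace, "n_pre")
  if (!"normalized" %in% names(trace)) abort("run frap_normalize() first.")
  post <- trace[-seq_len(n_pre), ]
  if (nrow(post) < 5L) abort("need >= 5 post-bleach frames to fit recovery.")
  tp <- post$time_s - post$time_s[1]
  y <- post$normalized
  f0_init <- y[1]
  finf_init <- mean(utils::tail(y, 3))
  # time to half recovery for the k initial value
  half <- f0_init + 0.5 * (finf_init - f0_init)
  idx <- which(y >= half)
  t_half <- if (length(idx) > 0L && tp[idx[1]] > 0) tp[idx[1]] else max(tp) / 4
  k_init <- max(log(2) / t_half, 1e-4)
  if (sd(y) < 1e-12) {
    # perfectly flat post-bleach curve: no recovery, Mf = 0 analytically
    # (undefined when the curve sits at 1, i.e. nothing was bleached)
    f0 <- y[1]
    mf_raw <- if (abs(1 - f0) < 1e-9) NA_real_ else 0
    return(structure(
      list(F0 = f0, Finf = f0, k = 0,
           mobile_fraction = mf_raw, mobile_fraction_raw = mf_raw,
           sse = 0, converged = TRUE, n_pre = as.integer(n_pre),
           time_post_s = tp, normalized_post = y,
           curve = tibble(time_s = trace$time_s, normalized = trace$normalized)),
      class = "frap_fit"
    ))
  }
  dat <- data.frame(tp = tp, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ F0 + (Finf - F0) * (1 - exp(-k * tp)),
      data = dat,
      start = list(F0 = f0_init, Finf = finf_init, k = k_init),
      lower = c(F0 = -Inf, Finf = -Inf, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pars <- c(F0 = NA_real_, Finf = NA_real_, k = NA_real_)
    sse <- NA_real_
    converged <- FALSE
    mf_raw <- NA_real_
  } else {
    pars <- coef(fit)
    sse <- sum(stats::residuals(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
    mf_raw <- unname((pars["Finf"] - pars["F0"]) / (1 - pars["F0"]))
  }
  structure(
    list(
      F0 = unname(pars["F0"]), Finf = unname(pars["Finf"]),
      k = unname(pars["k"]),
      mobile_fraction = if (is.na(mf_raw)) NA_real_ else min(max(mf_raw, 0), 1.05),
      mobile_fraction_raw = mf_raw,
      sse = sse, converged = converged,
      n_pre = as.integer(n_pre),
      time_post_s = tp, normalized_post = y,
      curve = tibble(time_s = trace$time_s, normalized = trace$normalized)
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> Mf = %.3f, k = %.4g /s, F0 = %.3f, Finf = %.3f (%s)\n",
    x$mobile_fraction, x$k, x$F0, x$Finf,
    if (isTRUE(x$converged)) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Tidy a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`F0`, `Finf`, `k`,
#'   `mobile_fraction`). `glance()`: one-row model summary.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("F0", "Finf", "k", "mobile_fraction"),
    estimate = c(x$F0, x$Finf, x$k, x$mobile_fraction)
  )
}

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    mobile_fraction = x$mobile_fraction,
    mobile_fraction_raw = x$mobile_fraction_raw,
    k = x$k, F0 = x$F0, Finf = x$Finf,
    sse = x$sse, converged = x$converged,
    n_post = length(x$time_post_s)
  )
}

#' Aggregate FRAP fits across granules
#'
#' Pools individual fits (fit-then-average): the group recovery curve is the
#' pointwise mean +/- SEM of the normalized curves on a common post-bleach
#' time grid (linear interpolation when grids differ), and the group mobile
#' fraction is the mean +/- SEM of the per-granule fits. A single fit
#' reports SEM as `NA`.
#'
#' @param fits List of `frap_fit` objects (optionally named), or a named
#'   list of such lists to compare groups.
#' @param interpolate Allow interpolation onto a common grid when the time
#'   grids differ; if `FALSE`, differing grids are an error.
#' @return List with `curve` (tibble: `group`, `time_s`, `mean`, `sem`,
#'   `n`) and `mobile_fraction` (tibble: `group`, `n`, `mean_mf`, `sem_mf`,
#'   `mean_k`, `sem_k`).
#' @export
aggregate_frap <- function(fits, interpolate = TRUE) {
  if (inherits(fits, "frap_fit")) fits <- list(fits)
  is_group_list <- !inherits(fits[[1]], "frap_fit")
  groups <- if (is_group_list) fits else list(all = fits)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  curve <- purrr::imap_dfr(groups, function(fl, gname) {
    grids <- purrr::map(fl, "time_post_s")
    common <- grids[[1]]
    same <- all(purrr::map_lgl(grids, ~ length(.x) == length(common) &&
                                 all(.x == common)))
    if (!same) {
      if (!interpolate) abort("fits have differing time grids; set `interpolate = TRUE`.")
      common <- sort(unique(unlist(grids)))
    }
    mat <- vapply(fl, function(f) {
      if (same) f$normalized_post
      else approx(f$time_post_s, f$normalized_post, xout = common, rule = 2)$y
    }, numeric(length(common)))
    mat <- matrix(mat, nrow = length(common))
    tibble(group = gname, time_s = common,
           mean = rowMeans(mat),
           sem = apply(mat, 1, sem),
           n = ncol(mat))
  })
  mf <- purrr::imap_dfr(groups, function(fl, gname) {
    mfs <- purrr::map_dbl(fl, "mobile_fraction")
    ks <- purrr::map_dbl(fl, "k")
    tibble(group = gname, n = length(fl),
           mean_mf = mean(mfs, na.rm = TRUE), sem_mf = sem(mfs),
           mean_k = mean(ks, na.rm = TRUE), sem_k = sem(ks))
  })
  list(curve = curve, mobile_fraction = mf)
}
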