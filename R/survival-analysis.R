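#' Kaplan-Meier estimate of granule persistence
#'
#' Product-limit estimator of the probability that a cell still contains
#' granules at time t, from per-cell times to complete disassembly with
#' right-censoring. Confidence intervals use the Greenwood variance on the
#' log-survival scale (the `survival` package's `conf.type = "log"`).
#'
#' @param records Tibble with columns `time_min` and `event` (TRUE =
#'   disassembly observed), e.g. from [sample_survival_cohort()] or
#'   [score_disassembly()]; an optional `group` column stratifies the fit.
#' @param conf_level Confidence level for the interval.
#' @return An `sg_km` object wrapping the `survfit` fit; see
#'   [tidy.sg_km()], [glance.sg_km()], [autoplot.sg_km()].
#' @examples
#' km <- kaplan_meier(tibble::tibble(time_min = c(1, 2, 3),
#'                                   event = c(TRUE, TRUE, TRUE)))
#' tidy(km)
#' @export
kaplan_meier <- function(records, conf_level = 0.95) {
  records <- as_tibble(records)
  if (!all(c("time_min", "event") %in% names(records))) {
    abort("`records` needs columns `time_min` and `event`.")
  }
  if (sum(records$event) == 0L) {
    warn("all records censored: survival is identically 1.")
  }
  has_group <- "group" %in% names(records) &&
    dplyr::n_distinct(records$group) > 1L
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time_min, event) ~ group, data = records,
                      conf.type = "log", conf.int = conf_level)
  } else {
    survival::survfit(survival::Surv(time_min, event) ~ 1, data = records,
                      conf.type = "log", conf.int = conf_level)
  }
  structure(list(fit = fit, records = records, grouped = has_group),
            class = "sg_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km An `sg_km` object (ungrouped).
#' @param times Times (minutes) at which to read off S(t).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  as.numeric(s$surv)
}

#' @export
print.sg_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x An `sg_km`.
#' @param ... Unused.
#' @return `tidy()`: the step function, one row per event/censoring time
#'   (`time`, `n_risk`, `n_event`, `estimate`, `conf_low`, `conf_high`, and
#'   `group` when stratified). `glance()`: per-group `n`, `events`,
#'   `median` survival time.
#' @export
tidy.sg_km <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) {
    rep("all", length(f$time))
  } else {
    rep(sub("^group=", "", names(f$strata)), f$strata)
  }
  tibble(group = strata, time = f$time, n_risk = f$n.risk,
         n_event = f$n.event, estimate = f$surv,
         conf_low = f$lower, conf_high = f$upper)
}

#' @rdname tidy.sg_km
#' @export
glance.sg_km <- function(x, ...) {
  s <- summary(x$fit)$table
  if (is.null(dim(s))) s <- matrix(s, 1, dimnames = list("all", names(s)))
  tibble(group = sub("^group=", "", rownames(s)),
         n = unname(s[, "records"]), events = unname(s[, "events"]),
         median = unname(s[, "median"]))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank comparison of two disassembly cohorts, via
#' `survival::survdiff`.
#'
#' @param records_a,records_b Survival record tibbles (`time_min`,
#'   `event`), one per group; or a single tibble with a `group` column in
#'   `records_a`.
#' @return One-row tibble: `chisq`, `df`, `p_value`, `n_a`, `n_b`.
#' @examples
#' a <- sample_survival_cohort(30, 0.04, 120, "fast", seed = 1)
#' b <- sample_survival_cohort(30, 0.01, 120, "slow", seed = 2)
#' logrank_test(a, b)
#' @export
logrank_test <- function(records_a, records_b = NULL) {
  dat <- if (is.null(records_b)) {
    as_tibble(records_a)
  } else {
    a <- as_tibble(records_a); b <- as_tibble(records_b)
    labs <- c(if ("group" %in% names(a)) a$group[1] else "a",
              if ("group" %in% names(b)) b$group[1] else "b")
    if (is.na(labs[1]) || is.na(labs[2]) || labs[1] == labs[2]) labs <- c("a", "b")
    a$group <- labs[1]; b$group <- labs[2]
    dplyr::bind_rows(a, b)
  }
  if (dplyr::n_distinct(dat$group) != 2L) {
    abort("log-rank test needs exactly 2 groups.")
  }
  per_group_events <- tapply(dat$event, dat$group, sum)
  if (any(per_group_events == 0L)) {
    abort("each group needs at least one observed event.")
  }
  sd_ <- survival::survdiff(survival::Surv(time_min, event) ~ group, data = dat)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  ns <- table(dat$group)
  tibble(chisq = sd_$chisq, df = 1, p_value = p,
         n_a = as.integer(ns[1]), n_b = as.integer(ns[2]))
}
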