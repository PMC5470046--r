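#' Specify a simulated FRAP experiment
#'
#' Describes a bleach-recovery time course for a square ROI (the assay uses
#' a 20 x 20 px, 2.7 x 2.7 um bleach square): `pre_bleach_frames` frames at
#' the resting level, an instantaneous bleach removing `bleach_depth` of the
#' ROI signal, then single-exponential recovery of a `true_mobile_fraction`
#' of the bleached signal at rate `true_rate_per_s`. Whole-field acquisition
#' photobleaching multiplies every signal by
#' `(1 - acquisition_loss_per_frame)^frame`.
#'
#' @param pre_bleach_frames Number of pre-bleach frames (>= 2).
#' @param post_bleach_frames Number of post-bleach frames.
#' @param frame_interval_s Seconds between frames.
#' @param bleach_depth Fraction of the pre-bleach ROI signal removed at the
#'   bleach, in \[0, 1\].
#' @param true_mobile_fraction Mobile fraction in \[0, 1\]: the fraction of
#'   bleached signal that recovers.
#' @param true_rate_per_s Recovery rate constant, 1/s.
#' @param acquisition_loss_per_frame Fractional whole-field photobleaching
#'   per frame, in \[0, 1).
#' @param noise_sd Gaussian noise sd added to every trace sample, a.u.
#' @param pre_level Resting ROI intensity, a.u.
#' @param reference_level Resting reference-region intensity, a.u.
#' @param background_level Constant background intensity, a.u.
#' @param seed Integer RNG seed.
#' @return A `frap_spec` list.
#' @seealso [simulate_frap()], [frap_normalize()], [frap_fit()]
#' @export
frap_spec <- function(pre_bleach_frames = 5L,
                      post_bleach_frames = 60L,
                      frame_interval_s = 1,
                      bleach_depth = 0.8,
                      true_mobile_fraction = 0.6,
                      true_rate_per_s = 0.1,
                      acquisition_loss_per_frame = 0.002,
                      noise_sd = 2,
                      pre_level = 100,
                      reference_level = 100,
                      background_level = 10,
                      seed = 1L) {
  spec <- list(
    pre_bleach_frames = as.integer(pre_bleach_frames),
    post_bleach_frames = as.integer(post_bleach_frames),
    frame_interval_s = frame_interval_s,
    bleach_depth = bleach_depth,
    true_mobile_fraction = true_mobile_fraction,
    true_rate_per_s = true_rate_per_s,
    acquisition_loss_per_frame = acquisition_loss_per_frame,
    noise_sd = noise_sd,
    pre_level = pre_level,
    reference_level = reference_level,
    background_level = background_level,
    seed = as.integer(seed)
  )
  class(spec) <- "frap_spec"
  validate_frap_spec(spec)
  spec
}

validate_frap_spec <- function(spec) {
  if (spec$pre_bleach_frames < 2L) abort("`pre_bleach_frames` must be >= 2.")
  if (spec$post_bleach_frames < 1L) abort("`post_bleach_frames` must be >= 1.")
  stopifnot_scalar_number(spec$frame_interval_s, "frame_interval_s", lower = 1e-9)
  stopifnot_scalar_number(spec$bleach_depth, "bleach_depth", 0, 1)
  stopifnot_scalar_number(spec$true_mobile_fraction, "true_mobile_fraction", 0, 1)
  stopifnot_scalar_number(spec$true_rate_per_s, "true_rate_per_s", lower = 0)
  stopifnot_scalar_number(spec$acquisition_loss_per_frame,
                          "acquisition_loss_per_frame", 0, 1 - 1e-9)
  stopifnot_scalar_number(spec$noise_sd, "noise_sd", lower = 0)
  invisible(spec)
}

#' Simulate a FRAP trace with known ground truth
#'
#' Generates the raw three-trace record consumed by the FRAP analysis:
#' bleach-ROI, reference, and background time courses. Before noise,
#' \deqn{roi(t) = L(t)\,[\,P(1-d) + d\,M_f(1-e^{-k t'})P\,] + B}
#' post-bleach (and \eqn{L(t) P + B} pre-bleach), where \eqn{P} is the
#' pre-bleach level, \eqn{d} the bleach depth, \eqn{M_f} the mobile
#' fraction, \eqn{k} the rate, \eqn{t'} the time since the first post-bleach
#' frame, \eqn{B} the background, and
#' \eqn{L(t) = (1-\mathrm{loss})^{\mathrm{frame}}} the acquisition-bleaching
#' envelope. The reference trace carries \eqn{L(t)} only; the background
#' trace is constant plus noise.
#'
#' @param spec A [frap_spec()].
#' @return A `frap_trace` tibble with columns `time_s`, `roi`, `reference`,
#'   `background` and attributes `n_pre` (pre-bleach frame count) and
#'   `truth` (the generating spec).
#' @examples
#' tr <- simulate_frap(frap_spec(true_mobile_fraction = 0.5, noise_sd = 0))
#' head(tr)
#' @export
simulate_frap <- function(spec) {
  validate_frap_spec(spec)
  n <- spec$pre_bleach_frames + spec$post_bleach_frames
  frame <- seq_len(n) - 1L
  time_s <- frame * spec$frame_interval_s
  L <- (1 - spec$acquisition_loss_per_frame)^frame
  post <- frame >= spec$pre_bleach_frames
  t_prime <- pmax(0, time_s - time_s[spec$pre_bleach_frames + 1L])
  P <- spec$pre_level
  d <- spec$bleach_depth
  recovery <- P * (1 - d) + d * spec$true_mobile_fraction *
    (1 - exp(-spec$true_rate_per_s * t_prime)) * P
  roi <- ifelse(post, L * recovery, L * P) + spec$background_level
  reference <- L * spec$reference_level + spec$background_level
  background <- rep(spec$background_level, n)
  local_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      roi <- roi + rnorm(n, 0, spec$noise_sd)
      reference <- reference + rnorm(n, 0, spec$noise_sd)
      background <- background + rnorm(n, 0, spec$noise_sd)
    }
    out <- tibble(time_s = time_s, roi = roi, reference = reference,
                  background = background)
    attr(out, "n_pre") <- spec$pre_bleach_frames
    attr(out, "truth") <- spec
    class(out) <- c("frap_trace", class(out))
    out
  })
}
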