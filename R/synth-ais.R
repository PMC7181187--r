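#' Generate a synthetic AIS fluorescence profile with known extent
#'
#' Emulates an AnkyrinG-like intensity profile along an AIS: bright at the
#' center, fading towards both ends. The requested `length_um` is the
#' ground-truth extent at the 20%-of-maximum rule, i.e. before noise the
#' intensity exceeds 20% of its peak exactly over a contiguous region of
#' that length. The analytic threshold crossings are stored in the truth
#' record.
#'
#' Shapes: `triangular` (linear ramps to zero), `plateau` (flat core with
#' linear ramps of length `ramp_um` on each side), `gaussian`.
#'
#' @param cfg a [sim_config()]; `profile_step` sets the arclength sampling.
#' @param length_um true 20%-extent of the AIS, um.
#' @param peak peak intensity, AU.
#' @param shape one of `"plateau"`, `"gaussian"`, `"triangular"`.
#' @param noise_sd additive Gaussian noise SD, AU (intensities are floored
#'   at zero after noise).
#' @param margin_um dark margin added on each side of the support, um.
#' @param ramp_um ramp length for the plateau shape, um.
#' @return list with elements `profile` ([fluorescence_profile()]) and
#'   `truth` (`true_start_um`, `true_end_um`, `true_length_um`, shape
#'   parameters).
#' @export
make_ais_profile <- function(cfg, length_um = 30, peak = 100,
                             shape = c("plateau", "gaussian", "triangular"),
                             noise_sd = 0, margin_um = 5, ramp_um = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  shape <- match.arg(shape)
  check_positive(length_um, "length_um")
  check_positive(peak, "peak")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  frac <- 0.2  # extent rule the truth is defined against

  # support = region of non-zero signal; crossings computed analytically
  if (shape == "triangular") {
    support <- length_um / (1 - frac)
    half <- support / 2
    ideal <- function(x) pmax(0, peak * (1 - abs(x - margin_um - half) / half))
    t0 <- margin_um + frac * half
    t1 <- margin_um + support - frac * half
  } else if (shape == "plateau") {
    core <- length_um - 2 * (1 - frac) * ramp_um
    if (core <= 0) stop_invalid("length_um too short for the plateau ramps")
    support <- core + 2 * ramp_um
    a <- margin_um           # support start
    ideal <- function(x) {
      up <- pmin(1, pmax(0, (x - a) / ramp_um))
      dn <- pmin(1, pmax(0, (a + support - x) / ramp_um))
      peak * pmin(up, dn)
    }
    t0 <- a + frac * ramp_um
    t1 <- a + support - frac * ramp_um
  } else { # gaussian
    sigma <- length_um / (2 * sqrt(2 * log(1 / frac)))
    support <- 2 * length_um   # sampled window around the peak
    ctr <- margin_um + support / 2
    ideal <- function(x) peak * exp(-(x - ctr)^2 / (2 * sigma^2))
    t0 <- ctr - length_um / 2
    t1 <- ctr + length_um / 2
  }

  x <- seq(0, support + 2 * margin_um, by = cfg$profile_step)
  y0 <- ideal(x)
  y <- with_cfg_seed(cfg, pmax(0, y0 + stats::rnorm(length(x), 0, noise_sd)))
  list(
    profile = fluorescence_profile(x, y, path_id = sprintf("sim-%s", shape)),
    truth = list(true_start_um = t0, true_end_um = t1,
                 true_length_um = t1 - t0, shape = shape,
                 peak = peak, fraction = frac, noise_sd = noise_sd,
                 ideal_intensity = y0)
  )
}
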