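#' Simulation configuration for the synthetic-data generators
#'
#' Bundles the acquisition geometry and noise settings shared by all
#' generators. Defaults mirror the acquisition settings the analyses
#' assume: confocal stacks with a 1 um z-step and voltage-imaging movies
#' at ~120 Hz, with the camera exposing dark frames before the LED turns
#' on and after it turns off.
#'
#' A fixed `seed` makes every generator deterministic: calling the same
#' generator twice with the same configuration yields byte-identical
#' output. Each generated object carries a `truth` record (ground truth)
#' that analysis functions never read; it exists solely so that tests can
#' score parameter recovery.
#'
#' @param seed integer RNG seed.
#' @param pixel_size_xy lateral pixel size, um/px.
#' @param z_step axial step between planes, um.
#' @param frame_rate voltage-imaging frame rate, Hz.
#' @param sampling_rate_hz electrophysiology sampling rate, Hz.
#' @param profile_step arclength sampling step for fluorescence profiles, um.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$frame_rate
sim_config <- function(seed = 1L,
                       pixel_size_xy = 0.2,
                       z_step = 1,
                       frame_rate = 120,
                       sampling_rate_hz = 50e3,
                       profile_step = 0.5) {
  if (length(seed) != 1L || !is.finite(seed)) stop_invalid("seed must be a single integer")
  check_positive(pixel_size_xy, "pixel_size_xy")
  check_positive(z_step, "z_step")
  check_positive(frame_rate, "frame_rate")
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(profile_step, "profile_step")
  structure(
    list(
      seed = as.integer(seed),
      pixel_size_xy = pixel_size_xy,
      z_step = z_step,
      frame_rate = frame_rate,
      sampling_rate_hz = sampling_rate_hz,
      profile_step = profile_step
    ),
    class = "sim_config"
  )
}

# Run a generator body under the config seed, restoring RNG state after.
with_cfg_seed <- function(cfg, expr) {
  withr::with_seed(cfg$seed, expr)
}
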