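#' Generate synthetic voltage-imaging repeat series
#'
#' Emulates GEVI ROI time series: each repeat is
#' `camera_offset + bleach(t) * (1 + response(t)) + noise`, where
#' `bleach` is a double-exponential photobleaching envelope active while
#' the LED is on, and `response` is a boxcar fractional-fluorescence
#' deflection inside the stimulus window. Dark frames (LED off) flank
#' the recording at both ends. Depolarizing responses have negative
#' amplitude: the indicator dims when the membrane depolarizes.
#'
#' @param cfg a [sim_config()]; `frame_rate` sets the frame grid.
#' @param n_repeats number of stimulus repeats (the acquisitions the
#'   analyses assume use 40-50).
#' @param bleach named vector `c(A1, tau1, A2, tau2)`; amplitudes AU,
#'   time constants s (measured from LED onset).
#' @param response_amp fractional response amplitude (dF/F units;
#'   negative = depolarizing).
#' @param response_onset_s,response_dur_s response window relative to
#'   LED onset, s.
#' @param camera_offset camera baseline offset, AU.
#' @param noise_sd Gaussian read-noise SD, AU.
#' @param led_dur_s LED-on duration, s.
#' @param dark_pre_frames,dark_post_frames dark frames before/after.
#' @param stimulated logical: `FALSE` makes reference (non-stimulation)
#'   repeats with no response.
#' @return list with `series` (class `repeat_series`: matrix `F`
#'   frames x repeats, `time_s`, `led_on`, `stim_window_s`,
#'   `frame_rate`) and `truth`.
#' @export
make_repeat_series <- function(cfg, n_repeats = 45,
                               bleach = c(A1 = 600, tau1 = 0.4, A2 = 400, tau2 = 4),
                               response_amp = -0.01,
                               response_onset_s = 0.5,
                               response_dur_s = 0.15,
                               camera_offset = 100,
                               noise_sd = 20,
                               led_dur_s = 1,
                               dark_pre_frames = 12L,
                               dark_post_frames = 12L,
                               stimulated = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (bleach[["tau1"]] <= 0 || bleach[["tau2"]] <= 0) {
    stop_invalid("bleach time constants must be positive")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  fr <- cfg$frame_rate
  n_on <- round(led_dur_s * fr)
  if (response_onset_s < 0 ||
      response_onset_s + response_dur_s > led_dur_s) {
    stop_invalid("response window must lie inside the LED-on span")
  }
  n <- dark_pre_frames + n_on + dark_post_frames
  time_s <- (seq_len(n) - 1L) / fr
  led_on <- c(rep(FALSE, dark_pre_frames), rep(TRUE, n_on),
              rep(FALSE, dark_post_frames))
  t_led <- time_s - time_s[dark_pre_frames + 1L]  # 0 at LED onset
  env <- ifelse(led_on,
                bleach[["A1"]] * exp(-t_led / bleach[["tau1"]]) +
                  bleach[["A2"]] * exp(-t_led / bleach[["tau2"]]), 0)
  resp <- if (stimulated) {
    response_amp * (t_led >= response_onset_s &
                      t_led < response_onset_s + response_dur_s & led_on)
  } else rep(0, n)
  clean <- camera_offset + env * (1 + resp)
  F <- with_cfg_seed(cfg, {
    m <- matrix(stats::rnorm(n * n_repeats, 0, noise_sd), n, n_repeats)
    m + clean
  })
  series <- structure(list(
    F = F, time_s = time_s, led_on = led_on,
    stim_window_s = time_s[dark_pre_frames + 1L] +
      c(response_onset_s, response_onset_s + response_dur_s),
    frame_rate = fr,
    dark_pre_frames = dark_pre_frames,
    dark_post_frames = dark_post_frames), class = "repeat_series")
  list(series = series,
       truth = list(response_amp = if (stimulated) response_amp else 0,
                    polarity = if (!stimulated || response_amp == 0) {
                      "none"
                    } else if (response_amp < 0) "depolarizing" else "hyperpolarizing",
                    bleach = bleach, camera_offset = camera_offset,
                    clean_trace = clean, noise_sd = noise_sd))
}
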