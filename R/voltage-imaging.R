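#' Subtract camera noise from a repeat series
#'
#' The camera baseline is estimated per repeat as the mean over a
#' 10-frame window with no LED illumination and subtracted from the
#' whole trace.
#'
#' @param series a `repeat_series` (see [make_repeat_series()]).
#' @param n_frames dark-window length, frames.
#' @return the series with `F` offset-corrected and an
#'   `camera_offset_est` vector attached.
#' @export
subtract_camera_noise <- function(series, n_frames = 10L) {
  stopifnot(inherits(series, "repeat_series"))
  dark <- which(!series$led_on)
  if (length(dark) < n_frames) {
    stop(errorCondition(sprintf("need >= %d dark frames", n_frames),
                        class = c("axq_no_dark_frames", "error")))
  }
  win <- dark[seq_len(n_frames)]
  offs <- colMeans(series$F[win, , drop = FALSE])
  series$F <- sweep(series$F, 2L, offs)
  series$camera_offset_est <- offs
  series
}

#' Fit a double-exponential photobleaching model
#'
#' `F(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)`, fitted by nonlinear least
#' squares to the LED-on frames, excluding the frames inside
#' `exclusion_window_s` (the expected evoked-response span) so the
#' response does not bias the envelope. Initialization is a
#' deterministic multi-start: tau pairs drawn from {0.1, 1, 10} x the
#' LED-on duration, amplitudes from a linear fit at fixed taus; the
#' start with the best refined residual wins. Taus are bounded to
#' [2 frames, 100 x duration].
#'
#' @param trace fluorescence trace of one repeat (camera-corrected), AU.
#' @param time_s frame times, s.
#' @param led_on logical LED mask.
#' @param exclusion_window_s `c(start, end)` in the same time base, or
#'   `NULL` to fit all LED-on frames.
#' @return object of class `bleach_model`: `coef` (A1, tau1, A2, tau2),
#'   `fitted` (envelope over all frames; NA where LED off), `rss`,
#'   `exclusion_window_s`.
#' @export
fit_bleach <- function(trace, time_s, led_on, exclusion_window_s = NULL) {
  use <- led_on
  if (!is.null(exclusion_window_s)) {
    use <- use & !(time_s >= exclusion_window_s[1] &
                     time_s <= exclusion_window_s[2])
  }
  if (sum(use) < 20L) stop_invalid("need >= 20 frames outside the exclusion window")
  t0 <- time_s[which(led_on)[1L]]
  tt <- time_s[use] - t0
  yy <- trace[use]
  dur <- diff(range(time_s[led_on]))
  dt <- stats::median(diff(time_s))
  lo_tau <- 2 * dt; hi_tau <- 100 * dur

  starts <- list()
  for (f1 in c(0.1, 1)) for (f2 in c(1, 10)) {
    if (f2 <= f1) next
    starts[[length(starts) + 1L]] <- c(tau1 = f1 * dur, tau2 = f2 * dur)
  }
  best <- NULL
  for (s in starts) {
    X <- cbind(exp(-tt / s[["tau1"]]), exp(-tt / s[["tau2"]]))
    a <- tryCatch(stats::coef(stats::lm.fit(X, yy)), error = function(e) c(1, 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ A1 * exp(-tt / tau1) + A2 * exp(-tt / tau2),
        start = list(A1 = unname(a[1]), tau1 = s[["tau1"]],
                     A2 = unname(a[2]), tau2 = s[["tau2"]]),
        lower = c(-Inf, lo_tau, -Inf, lo_tau),
        upper = c(Inf, hi_tau, Inf, hi_tau),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop(errorCondition("bleach fit failed to converge from any start",
                        class = c("axq_fit_failure", "error")))
  }
  cf <- stats::coef(best$fit)
  env <- rep(NA_real_, length(trace))
  env[led_on] <- cf[["A1"]] * exp(-(time_s[led_on] - t0) / cf[["tau1"]]) +
    cf[["A2"]] * exp(-(time_s[led_on] - t0) / cf[["tau2"]])
  structure(list(coef = cf, fitted = env, rss = best$rss,
                 exclusion_window_s = exclusion_window_s),
            class = "bleach_model")
}

#' Bleach-correct a repeat series and compute dF/F
#'
#' Per repeat: fit (or take) the bleach envelope, correct the trace, and
#' compute dF/F with F defined as the mean bleach-corrected fluorescence
#' of the last `baseline_frames` (10) frames before the evoked event.
#' Two correction forms are available: `"ratio"` (default,
#' `corrected = raw / fit`, invariant to multiplicative gain) and
#' `"subtractive"` (`corrected = raw - fit + mean(fit)`).
#'
#' @param series a camera-corrected `repeat_series`.
#' @param event_time_s evoked-event onset, s; defaults to the stimulus
#'   window start.
#' @param fits optional list of `bleach_model`s (one per repeat); fitted
#'   here (with the stimulus window excluded) when `NULL`.
#' @param method `"ratio"` or `"subtractive"`.
#' @param baseline_frames baseline length for F, frames.
#' @return list with `dff` (frames x repeats matrix, NA on dark frames),
#'   `time_s`, `led_on`, `event_time_s`, `method`, `fits`.
#' @export
bleach_correct_dff <- function(series,
                               event_time_s = series$stim_window_s[1],
                               fits = NULL,
                               method = c("ratio", "subtractive"),
                               baseline_frames = 10L) {
  stopifnot(inherits(series, "repeat_series"))
  method <- match.arg(method)
  led <- series$led_on
  pre_idx <- which(led & series$time_s < event_time_s)
  if (length(pre_idx) < baseline_frames) {
    stop_invalid("event_time_s leaves fewer than ", baseline_frames,
                 " LED-on baseline frames")
  }
  base_idx <- utils::tail(pre_idx, baseline_frames)
  nrep <- ncol(series$F)
  if (is.null(fits)) {
    excl <- c(series$stim_window_s[1], series$stim_window_s[2] + 0.05)
    fits <- lapply(seq_len(nrep), function(i)
      fit_bleach(series$F[, i], series$time_s, led, excl))
  }
  dff <- matrix(NA_real_, nrow(series$F), nrep)
  for (i in seq_len(nrep)) {
    env <- fits[[i]]$fitted
    if (method == "ratio") {
      corr <- series$F[, i] / env
    } else {
      corr <- series$F[, i] - env + mean(env[led], na.rm = TRUE)
    }
    f0 <- mean(corr[base_idx])
    dff[, i] <- (corr - f0) / f0
  }
  list(dff = dff, time_s = series$time_s, led_on = led,
       event_time_s = event_time_s, method = method, fits = fits,
       baseline_idx = base_idx)
}

#' Bleach correction trained on non-stimulation reference repeats
#'
#' For recordings whose responses are too long to leave enough baseline
#' for per-repeat fitting, the bleach model is fitted on reference
#' (non-stimulation) repeats over their full LED-on span and the
#' resulting envelope shape is applied to every stimulation repeat.
#'
#' @param series stimulation `repeat_series` (camera-corrected).
#' @param reference reference `repeat_series` (same frame grid).
#' @inheritParams bleach_correct_dff
#' @return as [bleach_correct_dff()], plus `reference_fit`.
#' @export
bleach_correct_by_reference <- function(series, reference,
                                        event_time_s = series$stim_window_s[1],
                                        method = c("ratio", "subtractive"),
                                        baseline_frames = 10L) {
  stopifnot(inherits(series, "repeat_series"),
            inherits(reference, "repeat_series"))
  if (ncol(reference$F) < 1L) stop_invalid("need >= 1 reference repeat")
  if (length(series$time_s) != length(reference$time_s) ||
      any(series$led_on != reference$led_on)) {
    stop(errorCondition("reference and stimulation frame grids differ",
                        class = c("axq_grid_mismatch", "error")))
  }
  ref_trace <- rowMeans(reference$F)
  ref_fit <- fit_bleach(ref_trace, reference$time_s, reference$led_on, NULL)
  # normalized envelope shape; per-repeat gain cancels in the ratio form
  # and is restored from each repeat's own baseline in the subtractive one
  fits <- lapply(seq_len(ncol(series$F)), function(i) {
    f <- ref_fit
    led <- series$led_on
    g <- stats::median(series$F[led, i] / ref_fit$fitted[led], na.rm = TRUE)
    f$fitted <- ref_fit$fitted * g
    f
  })
  out <- bleach_correct_dff(series, event_time_s, fits = fits,
                            method = method, baseline_frames = baseline_frames)
  out$reference_fit <- ref_fit
  out
}

#' Average dF/F repeats and smooth
#'
#' Frame-wise mean across repeats followed by a centered 3-frame moving
#' average; at the trace edges the window shrinks to the available
#' frames.
#'
#' @param dff_result result of [bleach_correct_dff()] (or a plain
#'   frames x repeats matrix).
#' @param window moving-average width, frames (odd).
#' @return list with `dff` (averaged, smoothed vector), `time_s`,
#'   `led_on` when available.
#' @export
average_and_smooth <- function(dff_result, window = 3L) {
  if (is.matrix(dff_result)) {
    m <- dff_result; time_s <- NULL; led <- NULL; ev <- NULL
  } else {
    m <- dff_result$dff; time_s <- dff_result$time_s
    led <- dff_result$led_on; ev <- dff_result$event_time_s
  }
  avg <- rowMeans(m)
  ok <- !is.na(avg)
  sm <- avg
  sm[ok] <- moving_average(avg[ok], window)
  list(dff = sm, time_s = time_s, led_on = led, event_time_s = ev,
       window = window)
}

#' Measure the response amplitude of an averaged dF/F trace
#'
#' Two readouts over the response window: the window mean (unbiased for
#' a sustained response; extremum readouts inherit an outward bias from
#' noise) and the signed extremum. A few frames are trimmed at both
#' window edges so the moving-average transition does not dilute the
#' mean.
#'
#' @param dff averaged dF/F vector.
#' @param time_s frame times, s.
#' @param window_s `c(start, end)` response window, s.
#' @param trim_frames frames trimmed from each window edge.
#' @return list with `mean_amp`, `peak_amp`, `n_frames`.
#' @export
response_amplitude <- function(dff, time_s, window_s, trim_frames = 2L) {
  idx <- which(time_s >= window_s[1] & time_s < window_s[2] & !is.na(dff))
  if (length(idx) <= 2 * trim_frames + 1L) {
    stop_invalid("response window too short after trimming")
  }
  core <- idx[(trim_frames + 1L):(length(idx) - trim_frames)]
  pk <- idx[which.max(abs(dff[idx]))]
  list(mean_amp = mean(dff[core]), peak_amp = dff[pk],
       n_frames = length(core))
}

#' Z-score a dF/F trace and detect time-locked events
#'
#' Z(t) = (x(t) - baseline mean) / baseline SD, with the baseline taken
#' over all pre-stimulus LED-on frames by default. An event is >= `m`
#' consecutive frames with |Z| > `k` (default 3 baseline SDs) inside the
#' response window (stimulus span plus `decay_allowance_s`, allowing for
#' the decay of GABAergic responses); its polarity is the sign of the
#' deflection at the extremum.
#'
#' @param dff averaged dF/F vector (e.g. from [average_and_smooth()]).
#' @param time_s frame times, s.
#' @param led_on logical LED mask.
#' @param stim_window_s `c(onset, offset)` of the stimulus, s.
#' @param k Z threshold.
#' @param m_consec persistence, frames.
#' @param baseline_idx baseline frame indices; default all pre-stimulus
#'   LED-on frames.
#' @param decay_allowance_s window extension past stimulus offset, s.
#' @return list with `z` (Z trace), `events` data.frame (`start_s`,
#'   `end_s`, `peak_z`, `polarity`), `baseline_idx`, `window_idx`, `k`.
#' @export
zscore_and_detect <- function(dff, time_s, led_on, stim_window_s,
                              k = 3, m_consec = 2L,
                              baseline_idx = NULL,
                              decay_allowance_s = 0.05) {
  if (is.null(baseline_idx)) {
    baseline_idx <- which(led_on & time_s < stim_window_s[1])
  }
  win_idx <- which(led_on & time_s >= stim_window_s[1] &
                     time_s <= stim_window_s[2] + decay_allowance_s)
  if (length(intersect(baseline_idx, win_idx))) {
    stop_invalid("baseline and response windows must be disjoint")
  }
  mu <- mean(dff[baseline_idx]); sdv <- stats::sd(dff[baseline_idx])
  if (!is.finite(sdv) || sdv == 0) {
    stop(errorCondition("zero baseline SD: Z scores undefined",
                        class = c("axq_zero_baseline_sd", "error")))
  }
  z <- (dff - mu) / sdv
  inwin <- rep(FALSE, length(dff)); inwin[win_idx] <- TRUE
  hit <- inwin & !is.na(z) & abs(z) > k
  runs <- true_runs(hit)
  runs <- runs[runs$end - runs$start + 1L >= m_consec, , drop = FALSE]
  events <- if (nrow(runs)) {
    do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      idx <- runs$start[r]:runs$end[r]
      pk <- idx[which.max(abs(z[idx]))]
      data.frame(start_s = time_s[runs$start[r]], end_s = time_s[runs$end[r]],
                 peak_z = z[pk],
                 polarity = if (z[pk] < 0) "negative" else "positive")
    }))
  } else {
    data.frame(start_s = numeric(), end_s = numeric(), peak_z = numeric(),
               polarity = character())
  }
  list(z = z, events = events, baseline_idx = baseline_idx,
       window_idx = win_idx, k = k, m_consec = m_consec)
}

#' Classify a voltage-imaging response
#'
#' The indicator dims on depolarization, so a significant negative
#' fluorescence event is a depolarizing response, a significant positive
#' event is hyperpolarizing, and absence of a time-locked event is
#' non-responsive (presumed shunting).
#'
#' @inheritParams zscore_and_detect
#' @return list with `classification` (one of `"depolarizing"`,
#'   `"hyperpolarizing"`, `"nonresponsive_shunting"`), `peak_z`, and the
#'   underlying detection result.
#' @export
classify_response <- function(dff, time_s, led_on, stim_window_s,
                              k = 3, m_consec = 2L,
                              decay_allowance_s = 0.05) {
  det <- zscore_and_detect(dff, time_s, led_on, stim_window_s,
                           k = k, m_consec = m_consec,
                           decay_allowance_s = decay_allowance_s)
  if (nrow(det$events) == 0L) {
    cls <- "nonresponsive_shunting"; pk <- NA_real_
  } else {
    pk <- det$events$peak_z[which.max(abs(det$events$peak_z))]
    cls <- if (pk < 0) "depolarizing" else "hyperpolarizing"
  }
  list(classification = cls, peak_z = pk, detection = det)
}
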