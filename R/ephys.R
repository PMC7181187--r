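#' Detect action-potential times in a current-clamp sweep
#'
#' Spikes are upward crossings of `threshold_mv` (default 0 mV) separated
#' by at least `refractory_ms`; the crossing time is refined by linear
#' interpolation between the flanking samples.
#'
#' @param voltage_mv numeric voltage trace, mV.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param threshold_mv crossing level, mV.
#' @param refractory_ms minimum separation between detections, ms.
#' @return numeric vector of spike times, s.
#' @export
detect_spikes <- function(voltage_mv, sampling_rate_hz,
                          threshold_mv = 0, refractory_ms = 1) {
  dt <- 1 / sampling_rate_hz
  v <- voltage_mv
  up <- which(v[-1L] >= threshold_mv & v[-length(v)] < threshold_mv)
  if (!length(up)) return(numeric(0))
  frac <- (threshold_mv - v[up]) / (v[up + 1L] - v[up])
  times <- (up - 1L + frac) * dt
  keep <- c(TRUE, diff(times) >= refractory_ms / 1e3)
  # greedy refractory: drop crossings too close to the last kept one
  out <- numeric(0); last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory_ms / 1e3) { out <- c(out, tt); last <- tt }
  }
  out
}

#' Build an input-output curve from a current-step protocol
#'
#' Per step, AP frequency = spike count / step duration. Two abscissae
#' are returned: injected current (pA) and current density (pA/pF, the
#' current normalized by cell capacitance, a proxy for cell size).
#'
#' @param sweep_set a `patch_sweeps` object with a `current_steps`
#'   protocol (see [make_patch_sweeps()]).
#' @param threshold_mv,refractory_ms passed to [detect_spikes()].
#' @return data.frame with `current_pa`, `current_density_pa_pf`,
#'   `n_spikes`, `ap_freq_hz`. When capacitance is missing the density
#'   column is `NA` with a warning.
#' @export
build_io_curve <- function(sweep_set, threshold_mv = 0, refractory_ms = 1) {
  stopifnot(inherits(sweep_set, "patch_sweeps"),
            sweep_set$protocol$type == "current_steps")
  p <- sweep_set$protocol
  on <- p$step_on_s; off <- p$step_on_s + p$step_dur_s
  counts <- vapply(sweep_set$sweeps, function(v) {
    st <- detect_spikes(v, sweep_set$sampling_rate_hz,
                        threshold_mv, refractory_ms)
    sum(st >= on & st < off + 0.01)
  }, numeric(1))
  cap <- sweep_set$capacitance_pf
  dens <- if (is.null(cap) || !is.finite(cap) || cap <= 0) {
    warning("capacitance missing or non-positive: density axis omitted")
    rep(NA_real_, length(counts))
  } else p$step_pa / cap
  data.frame(current_pa = p$step_pa,
             current_density_pa_pf = dens,
             n_spikes = counts,
             ap_freq_hz = counts / p$step_dur_s)
}

#' Voltage threshold from the first peak of the jerk
#'
#' The spike threshold is the membrane voltage at the time of the first
#' peak of the jerk (third time-derivative of voltage). The trace is
#' smoothed with a Savitzky-Golay local-polynomial filter and the third
#' derivative taken from the same filter; the first local maximum of the
#' jerk that exceeds `prominence_frac` of the window's jerk maximum,
#' before the AP peak, marks the threshold.
#'
#' @param voltage_mv voltage trace, mV.
#' @param sampling_rate_hz sampling rate, Hz (>= 10 kHz).
#' @param spike_time_s detected spike time (e.g. from [detect_spikes()]), s.
#' @param pre_window_ms search window length before the spike, ms.
#' The peak is located in two stages: a wide filter window gives a
#' robust first localization, then the jerk is re-estimated with a
#' narrower window around that point, which removes the systematic
#' early shift a wide window imposes on the sharply asymmetric onset
#' lobe. The final peak position is refined to sub-sample precision by
#' parabolic interpolation.
#'
#' @param sg_width_ms Savitzky-Golay window of the localization stage, ms.
#' @param sg_order polynomial order of the filter.
#' @param refine_width_ms,refine_order filter settings of the refinement
#'   stage (narrower window, applied only near the localized peak).
#' @param prominence_frac jerk-peak acceptance floor, as a fraction of the
#'   maximum jerk in the window.
#' @param noise_mult the floor is additionally kept above `noise_mult`
#'   robust (MAD-based) SDs of the jerk over the search window, so that
#'   baseline noise wiggles in the third derivative are never accepted
#'   as the onset peak.
#' @return list with `threshold_mv`, `threshold_time_s`, `jerk` (the
#'   smoothed third derivative over the window) and `window_time_s`.
#' @export
voltage_threshold_jerk <- function(voltage_mv, sampling_rate_hz, spike_time_s,
                                   pre_window_ms = 5, sg_width_ms = 0.7,
                                   sg_order = 6, prominence_frac = 0.2,
                                   noise_mult = 4.5,
                                   refine_width_ms = 0.4, refine_order = 6) {
  if (sampling_rate_hz < 10e3) stop_invalid("sampling rate must be >= 10 kHz")
  dt <- 1 / sampling_rate_hz
  n <- length(voltage_mv)
  i_spk <- round(spike_time_s / dt) + 1L
  if (i_spk < 2L || i_spk > n) stop_invalid("spike_time_s outside the trace")
  # AP peak: first local max at/after the crossing
  i_pk <- i_spk
  while (i_pk < n && voltage_mv[i_pk + 1L] >= voltage_mv[i_pk]) i_pk <- i_pk + 1L
  i0 <- max(1L, i_spk - round(pre_window_ms / 1e3 / dt))
  seg <- voltage_mv[i0:i_pk]

  width <- max(sg_order + 2L, round(sg_width_ms / 1e3 / dt))
  if (width %% 2L == 0L) width <- width + 1L
  if (width > length(seg)) stop_invalid("window too short for the filter width")
  vs <- signal::sgolayfilt(seg, p = sg_order, n = width, m = 0)
  jerk <- signal::sgolayfilt(seg, p = sg_order, n = width, m = 3, ts = dt)

  # drop filter edge effects
  valid <- (width %/% 2L + 1L):(length(seg) - width %/% 2L)
  if (length(valid) < 3L) stop_invalid("window too short after edge trimming")
  jv <- jerk[valid]
  # jerk noise level from the early (pre-onset) part of the window: the
  # spike sits at the window's end, so the first stretch is baseline
  base_n <- max(10L, floor(0.6 * length(jv)))
  noise_sd <- stats::mad(jv[seq_len(base_n)])
  floor_j <- max(prominence_frac * max(jv), noise_mult * noise_sd)
  loc <- which(diff(sign(diff(jv))) < 0) + 1L  # interior local maxima
  loc <- loc[jv[loc] >= floor_j & jv[loc] > 0]
  if (!length(loc)) {
    stop(errorCondition("no qualifying jerk peak before the AP peak",
                        class = c("axq_no_threshold", "error")))
  }
  i_thr <- valid[loc[1L]]

  # refinement stage: narrow window around the localized peak
  w2 <- max(refine_order + 2L, round(refine_width_ms / 1e3 / dt))
  if (w2 %% 2L == 0L) w2 <- w2 + 1L
  if (w2 < width && w2 < length(seg)) {
    vs2 <- signal::sgolayfilt(seg, p = refine_order, n = w2, m = 0)
    jerk2 <- signal::sgolayfilt(seg, p = refine_order, n = w2, m = 3, ts = dt)
    half <- round(0.25e-3 / dt)
    near <- max(w2 %/% 2L + 1L, i_thr - half):
      min(length(seg) - w2 %/% 2L, i_thr + half)
    if (length(near) >= 3L) {
      jn <- jerk2[near]
      loc2 <- which(diff(sign(diff(jn))) < 0) + 1L
      if (length(loc2)) {
        i_thr <- near[loc2[which.max(jn[loc2])]]
        vs <- vs2; jerk <- jerk2
      }
    }
  }

  # sub-sample refinement: parabola through the three samples around the
  # peak, then linear interpolation of the smoothed voltage
  frac <- 0
  if (i_thr > 1L && i_thr < length(seg)) {
    a <- jerk[i_thr - 1L]; b <- jerk[i_thr]; cc <- jerk[i_thr + 1L]
    den <- a - 2 * b + cc
    if (den < 0) frac <- max(-0.5, min(0.5, 0.5 * (a - cc) / den))
  }
  v_thr <- if (frac >= 0) {
    vs[i_thr] + frac * (vs[min(i_thr + 1L, length(seg))] - vs[i_thr])
  } else {
    vs[i_thr] + frac * (vs[i_thr] - vs[max(i_thr - 1L, 1L)])
  }
  list(threshold_mv = v_thr,
       threshold_time_s = (i0 - 1L + i_thr - 1L + frac) * dt,
       jerk = jerk, window_time_s = (seq_along(seg) + i0 - 2L) * dt)
}

#' Per-cell voltage threshold: median over all APs in a sweep
#'
#' Runs [voltage_threshold_jerk()] on every detected spike and returns
#' the median threshold. Single-AP estimates occasionally lock onto a
#' noise wiggle of the third derivative; the per-cell median is the
#' robust summary a threshold measurement reports.
#'
#' @inheritParams voltage_threshold_jerk
#' @param ... passed through to [voltage_threshold_jerk()].
#' @return list with `threshold_mv` (median), `per_spike_mv`, `n_spikes`,
#'   `n_used` (spikes with a successful estimate).
#' @export
cell_voltage_threshold <- function(voltage_mv, sampling_rate_hz, ...) {
  st <- detect_spikes(voltage_mv, sampling_rate_hz)
  if (!length(st)) {
    stop(errorCondition("no spikes detected",
                        class = c("axq_no_threshold", "error")))
  }
  ths <- vapply(st, function(x) {
    tryCatch(voltage_threshold_jerk(voltage_mv, sampling_rate_hz, x,
                                    ...)$threshold_mv,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(ths))) {
    stop(errorCondition("no spike yielded a qualifying jerk peak",
                        class = c("axq_no_threshold", "error")))
  }
  list(threshold_mv = stats::median(ths, na.rm = TRUE),
       per_spike_mv = ths, n_spikes = length(st),
       n_used = sum(!is.na(ths)))
}

#' Evoked PSC amplitude from averaged sweeps
#'
#' Each sweep is baseline-subtracted (mean over the pre-stimulus span),
#' the first `n_average` sweeps (default 15) are averaged, and the
#' extremum of the mean trace in the post-stimulus window is returned.
#'
#' @param sweep_set a `patch_sweeps` voltage-clamp object.
#' @param stim_time_s stimulus onset, s; defaults to the protocol value.
#' @param n_average number of sweeps to average.
#' @param window_s response window length after the stimulus, s.
#' @return list with `amplitude_pa` (signed extremum), `magnitude_pa`,
#'   `peak_time_s`, `n_used`, `mean_trace`, `baseline_sd`.
#' @export
evoked_psc_amplitude <- function(sweep_set,
                                 stim_time_s = sweep_set$protocol$stim_time_s,
                                 n_average = 15, window_s = 0.05) {
  stopifnot(inherits(sweep_set, "patch_sweeps"))
  nsw <- length(sweep_set$sweeps)
  n_used <- min(n_average, nsw)
  if (nsw < n_average) {
    warning(sprintf("only %d sweeps available; averaging %d", nsw, n_used))
  }
  t <- sweep_set$time_s
  pre <- t < stim_time_s
  if (!any(pre)) stop_invalid("no pre-stimulus baseline available")
  mat <- vapply(sweep_set$sweeps[seq_len(n_used)],
                function(v) v - mean(v[pre]), numeric(length(t)))
  mean_trace <- rowMeans(mat)
  win <- t >= stim_time_s & t <= stim_time_s + window_s
  ext <- which.max(abs(mean_trace[win]))
  amp <- mean_trace[win][ext]
  list(amplitude_pa = amp, magnitude_pa = abs(amp),
       peak_time_s = t[win][ext], n_used = n_used,
       mean_trace = mean_trace, baseline_sd = stats::sd(mean_trace[pre]))
}

#' Release failure rate across stimulation sweeps
#'
#' A sweep is a success when the absolute post-stimulus deflection from
#' its own baseline exceeds `k` baseline SDs within the response window;
#' otherwise it is a failure (absence of a postsynaptic response to the
#' light stimulus). Cells with fewer than two successes are excluded
#' rather than scored.
#'
#' The trace is smoothed at the PSC rise-time scale before the peak is
#' compared against the baseline SD of the same smoothed trace;
#' comparing raw pointwise maxima against the SD would flag noise
#' excursions as responses in any window of realistic length.
#'
#' @inheritParams evoked_psc_amplitude
#' @param k success criterion in baseline SDs.
#' @param smooth_ms pre-smoothing window, ms.
#' @param direction expected response direction: `"negative"` (inward,
#'   default), `"positive"`, or `"both"`.
#' @return list with `status` (`"ok"` or `"excluded"`), `failure_rate`
#'   (NA when excluded), `n_success`, `n_failure`, `success` flags.
#' @export
failure_rate <- function(sweep_set,
                         stim_time_s = sweep_set$protocol$stim_time_s,
                         k = 3, window_s = 0.05, smooth_ms = 5,
                         direction = c("negative", "positive", "both")) {
  stopifnot(inherits(sweep_set, "patch_sweeps"))
  direction <- match.arg(direction)
  nsw <- length(sweep_set$sweeps)
  if (nsw < 2L) stop_invalid("at least 2 sweeps required")
  t <- sweep_set$time_s
  pre <- t < stim_time_s
  win <- t >= stim_time_s & t <= stim_time_s + window_s
  wlen <- max(3L, round(smooth_ms / 1e3 * sweep_set$sampling_rate_hz))
  if (wlen %% 2L == 0L) wlen <- wlen + 1L
  sm <- lapply(sweep_set$sweeps, moving_average, width = wlen)
  # pooled baseline SD: per-sweep estimates have too few effective
  # degrees of freedom once the noise is smoothed
  s_pool <- stats::sd(unlist(lapply(sm, function(vs) vs[pre] - mean(vs[pre]))))
  success <- vapply(sm, function(vs) {
    b <- mean(vs[pre])
    defl <- switch(direction,
                   negative = -(vs[win] - b),
                   positive = vs[win] - b,
                   both = abs(vs[win] - b))
    max(defl) > k * s_pool
  }, logical(1))
  ns <- sum(success)
  if (ns < 2L) {
    return(list(status = "excluded", failure_rate = NA_real_,
                n_success = ns, n_failure = nsw - ns, success = success))
  }
  list(status = "ok", failure_rate = (nsw - ns) / nsw,
       n_success = ns, n_failure = nsw - ns, success = success)
}

#' Build the PSC matching template
#'
#' Difference-of-exponentials waveform with a zero baseline before the
#' waveform: rise 1 ms, decay 20 ms, 1 ms zero-baseline, 40 ms total by
#' default. The waveform is normalized to unit peak and signed by
#' `sign` (-1 for inward currents).
#'
#' @param sampling_rate_hz sampling rate, Hz.
#' @param rise_ms,decay_ms,baseline_ms,total_ms template kinetics, ms.
#' @param sign +1 or -1 (event polarity).
#' @return numeric template vector.
#' @export
psc_template <- function(sampling_rate_hz, rise_ms = 1, decay_ms = 20,
                         baseline_ms = 1, total_ms = 40, sign = -1) {
  if (!(rise_ms < decay_ms && decay_ms < total_ms && rise_ms > 0 &&
          baseline_ms > 0)) {
    stop_invalid("need 0 < rise < decay < total and baseline > 0")
  }
  dt_ms <- 1e3 / sampling_rate_hz
  u <- seq(0, total_ms - dt_ms, by = dt_ms) - baseline_ms
  g <- ifelse(u >= 0, exp(-u / decay_ms) - exp(-u / rise_ms), 0)
  tpk <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  sign * g / (exp(-tpk / decay_ms) - exp(-tpk / rise_ms))
}

#' Sliding template-matching detection criterion (Clements-Bekkers)
#'
#' At every lag the template is optimally scaled and offset onto the
#' trace by least squares; the detection criterion is the fitted scale
#' divided by the standard error of the fit. Computed with sliding sums
#' so the whole trace is scored in one pass.
#'
#' @param trace numeric trace.
#' @param template template vector (see [psc_template()]).
#' @return list with vectors `scale`, `offset`, `criterion`, one value
#'   per lag (`length(trace) - length(template) + 1`).
#' @export
cb_criterion <- function(trace, template) {
  N <- length(template)
  L <- length(trace)
  if (N > L) stop_invalid("template longer than trace")
  sw <- sum(template); sw2 <- sum(template^2)
  ones <- rep(1, N)
  sx <- as.numeric(stats::filter(trace, ones, sides = 1))[N:L]
  sx2 <- as.numeric(stats::filter(trace^2, ones, sides = 1))[N:L]
  sxw <- as.numeric(stats::filter(trace, rev(template), sides = 1))[N:L]
  scale <- (sxw - sx * sw / N) / (sw2 - sw^2 / N)
  offset <- (sx - scale * sw) / N
  sse <- sx2 + scale^2 * sw2 + N * offset^2 -
    2 * scale * sxw - 2 * offset * sx + 2 * scale * offset * sw
  se <- sqrt(pmax(sse, 0) / (N - 1))
  list(scale = scale, offset = offset, criterion = scale / se)
}

#' Detect spontaneous PSCs by template matching
#'
#' Scaled-template sliding detection: events are lags where the
#' detection criterion exceeds `threshold` (default 3), collapsed to the
#' best lag per super-threshold run, with runs closer than the template
#' rise time merged.
#'
#' @param trace voltage-clamp current trace, pA.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param threshold detection-criterion threshold. Not specified by the
#'   published analysis; 3 is the field-standard default and the value
#'   used is echoed in the result.
#' @param rise_ms,decay_ms,baseline_ms,total_ms,sign template settings,
#'   see [psc_template()].
#' @param min_separation_ms minimum separation between reported events;
#'   defaults to the template decay time, which merges split
#'   super-threshold runs over a single event.
#' @return list with `events` data.frame (`onset_s`, `amplitude`,
#'   `criterion`), `threshold`, `criterion_trace`.
#' @export
detect_spontaneous_pscs <- function(trace, sampling_rate_hz, threshold = 3,
                                    rise_ms = 1, decay_ms = 20,
                                    baseline_ms = 1, total_ms = 40,
                                    sign = -1, min_separation_ms = decay_ms) {
  w <- psc_template(sampling_rate_hz, rise_ms, decay_ms, baseline_ms,
                    total_ms, sign)
  cb <- cb_criterion(trace, w)
  dc <- cb$criterion
  dt <- 1 / sampling_rate_hz
  hit <- !is.na(dc) & dc > threshold
  runs <- true_runs(hit)
  ev <- lapply(seq_len(nrow(runs)), function(r) {
    idx <- runs$start[r]:runs$end[r]
    best <- idx[which.max(dc[idx])]
    c(lag = best, dc = dc[best], scale = cb$scale[best])
  })
  min_sep <- min_separation_ms / 1e3
  onset <- numeric(0); amp <- numeric(0); crit <- numeric(0)
  last <- -Inf
  for (e in ev) {
    t_on <- (e[["lag"]] - 1L) * dt + baseline_ms / 1e3
    if (t_on - last >= min_sep) {
      onset <- c(onset, t_on)
      amp <- c(amp, sign * e[["scale"]])
      crit <- c(crit, e[["dc"]])
      last <- t_on
    }
  }
  list(events = data.frame(onset_s = onset, amplitude = amp,
                           criterion = crit),
       threshold = threshold, criterion_trace = dc)
}
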