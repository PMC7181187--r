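# Synthetic patch-clamp sweeps with analytic ground truth.
#
# The AP kernel is a sum of two logistic sigmoids (upstroke, downstroke).
# For a logistic A*sigmoid((t-c)/r) the third time-derivative has its
# first local maximum where the sigmoid equals s1 = 1/2 - sqrt(6)/6 of
# its amplitude (root of 1 - 12 s + 12 s^2), i.e. at t = c + x1*r with
# x1 = logit(s1). The upstroke amplitude is solved numerically so that
# the membrane voltage at the exact first jerk peak of the full kernel
# equals the requested true threshold, making the "first peak of the
# jerk" ground truth analytic rather than an empirical byproduct.

S1_LOGISTIC <- 0.5 - sqrt(6) / 6
X1_LOGISTIC <- log(S1_LOGISTIC / (1 - S1_LOGISTIC))

# Amplifier low-pass: signals filtered at 10 kHz before sampling.
# Patch amplifiers use Bessel filters for their ringing-free, nearly
# Gaussian step response; emulated here with a Gaussian FIR (-3 dB at
# `cutoff_hz`), which is zero-phase and monotone. Noop when the cutoff
# is at/above Nyquist.
acquisition_filter <- function(x, fs, cutoff_hz = 10e3) {
  if (cutoff_hz >= fs / 2) return(x)
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_hz) * fs  # samples
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

# Membrane + electrode voltage noise: Gaussian, band-limited to the low
# kilohertz range by the membrane/electrode RC (white noise at the full
# sampling bandwidth is unphysical in current clamp). Gaussian-filtered
# white noise rescaled to the requested RMS.
membrane_noise <- function(n, sd, fs, band_hz = 1e3) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- acquisition_filter(w, fs, band_hz)
  f / stats::sd(f) * sd
}

logistic <- function(x) 1 / (1 + exp(-x))

# third derivative of logistic(x) wrt x
logistic_d3 <- function(x) {
  s <- logistic(x)
  s * (1 - s) * (1 - 6 * s + 6 * s^2)
}

# AP kernel value and jerk at time u (ms) relative to kernel origin.
ap_kernel <- function(u, dv_up, r_up, dv_dn, r_dn, t_dn) {
  dv_up * logistic(u / r_up) - dv_dn * logistic((u - t_dn) / r_dn)
}
ap_kernel_jerk <- function(u, dv_up, r_up, dv_dn, r_dn, t_dn) {
  dv_up / r_up^3 * logistic_d3(u / r_up) -
    dv_dn / r_dn^3 * logistic_d3((u - t_dn) / r_dn)
}

# First local maximum of the analytic kernel jerk (ms relative to origin).
ap_first_jerk_peak <- function(dv_up, r_up, dv_dn, r_dn, t_dn) {
  g <- function(u) ap_kernel_jerk(u, dv_up, r_up, dv_dn, r_dn, t_dn)
  guess <- X1_LOGISTIC * r_up
  stats::optimize(g, interval = c(guess - r_up, guess + r_up),
                  maximum = TRUE, tol = 1e-10)$maximum
}

#' Generate synthetic patch-clamp sweeps with embedded ground truth
#'
#' Three protocols are emulated:
#' \describe{
#'   \item{`current_steps`}{current-clamp sweeps with square current
#'     injections of increasing amplitude (10 pA steps by default). A
#'     passive charging baseline carries phenomenological AP waveforms;
#'     spike count grows linearly above rheobase. The true voltage
#'     threshold (voltage at the first peak of the third derivative) is
#'     exactly `true_threshold_mv` for every AP.}
#'   \item{`opto_psc`}{voltage-clamp sweeps with a light-evoked inward
#'     GABAergic PSC (difference of exponentials, rise 1 ms / decay
#'     20 ms) present on each sweep with probability `1 - failure_prob`.}
#'   \item{`spontaneous`}{one long voltage-clamp trace with Poisson-like
#'     spontaneous PSCs at `psc_rate_hz`, minimum separation 50 ms.}
#' }
#'
#' @param cfg a [sim_config()].
#' @param protocol one of `"current_steps"`, `"opto_psc"`, `"spontaneous"`.
#' @param true_threshold_mv AP voltage threshold ground truth, mV.
#' @param step_pa current step amplitudes, pA.
#' @param step_dur_s step duration, s.
#' @param capacitance_pf cell capacitance, pF.
#' @param n_sweeps number of sweeps (opto protocol).
#' @param stim_time_s light-stimulus onset within each sweep, s.
#' @param psc_amplitude_pa PSC peak amplitude (magnitude), pA.
#' @param psc_rise_ms,psc_decay_ms PSC kinetics, ms.
#' @param failure_prob per-sweep release-failure probability.
#' @param amp_cv coefficient of variation of PSC amplitudes.
#' @param duration_s trace duration (spontaneous protocol), s.
#' @param psc_rate_hz spontaneous event rate, Hz.
#' @param noise_sd noise SD (mV in current clamp, pA in voltage clamp).
#' @param sampling_rate_hz sampling rate; defaults to the configured rate.
#' @return list with `sweeps` (class `patch_sweeps`) and `truth`.
#' @export
make_patch_sweeps <- function(cfg,
                              protocol = c("current_steps", "opto_psc", "spontaneous"),
                              true_threshold_mv = -42,
                              step_pa = seq(0, 200, by = 10),
                              step_dur_s = 0.5,
                              capacitance_pf = 80,
                              n_sweeps = 20,
                              stim_time_s = 0.1,
                              psc_amplitude_pa = 50,
                              psc_rise_ms = 1, psc_decay_ms = 20,
                              failure_prob = 0,
                              amp_cv = 0.2,
                              duration_s = 60,
                              psc_rate_hz = 0.5,
                              noise_sd = 0.5,
                              sampling_rate_hz = cfg$sampling_rate_hz) {
  stopifnot(inherits(cfg, "sim_config"))
  protocol <- match.arg(protocol)
  check_fraction(failure_prob, "failure_prob")
  if (sampling_rate_hz < 10e3) stop_invalid("sampling rate must be >= 10 kHz")
  fs <- sampling_rate_hz
  dt <- 1 / fs

  if (protocol == "current_steps") {
    el <- -70; rm_mohm <- 300; taum_s <- 0.02
    # inter-spike baseline sits just below threshold during firing
    vbase_cap <- true_threshold_mv - 10
    pre_s <- 0.12; post_s <- 0.1
    rheobase_pa <- (true_threshold_mv - el) / rm_mohm * 1e3
    gain_spk_per_pa <- 0.15

    # kernel shape constants (ms); upstroke gives max dV/dt ~ 220 mV/ms
    r_up <- 0.12; r_dn <- 0.35; t_dn <- 1.8
    n <- round((pre_s + step_dur_s + post_s) * fs)
    t <- (seq_len(n) - 1L) * dt
    on <- pre_s; off <- pre_s + step_dur_s

    sweeps <- vector("list", length(step_pa))
    truth_spikes <- vector("list", length(step_pa))
    for (si in seq_along(step_pa)) {
      ipa <- step_pa[si]
      vss <- el + ipa * rm_mohm / 1e3
      vb <- min(vss, vbase_cap)
      v <- el +
        (vb - el) * (1 - exp(-(t - on) / taum_s)) * (t >= on & t < off)
      # relaxation after the step
      voff <- el + (vb - el) * (1 - exp(-step_dur_s / taum_s))
      v[t >= off] <- el + (voff - el) * exp(-(t[t >= off] - off) / taum_s)

      nspk <- if (ipa >= rheobase_pa && vss > true_threshold_mv) {
        max(1L, floor(gain_spk_per_pa * (ipa - rheobase_pa)))
      } else 0L
      spike_t <- numeric(0); thr_t <- numeric(0)
      if (nspk > 0L) {
        # equal up/down amplitudes: the kernel returns exactly to baseline
        # after the AP, so stacked spikes do not drift the baseline.
        # Solve the amplitude so V at the exact first jerk peak equals
        # the requested threshold.
        f <- function(dv) {
          u1 <- ap_first_jerk_peak(dv, r_up, dv, r_dn, t_dn)
          vb + ap_kernel(u1, dv, r_up, dv, r_dn, t_dn) - true_threshold_mv
        }
        dv0 <- (true_threshold_mv - vb) / S1_LOGISTIC
        dv_up <- stats::uniroot(f, c(0.7 * dv0, 1.5 * dv0), tol = 1e-10)$root
        dv_dn <- dv_up
        u1 <- ap_first_jerk_peak(dv_up, r_up, dv_dn, r_dn, t_dn)

        first <- on + 6 * taum_s
        last <- off - 0.005
        thr_t <- seq(first, last, length.out = nspk + 1L)[seq_len(nspk)]
        for (tk in thr_t) {
          u_ms <- (t - tk) * 1e3 + u1  # kernel time; jerk peak lands at tk
          win <- u_ms > -8 & u_ms < 12
          v[win] <- v[win] + ap_kernel(u_ms[win], dv_up, r_up, dv_dn, r_dn, t_dn)
        }
        # analytic upward 0 mV crossing of each kernel on the flat baseline
        cross <- stats::uniroot(function(u)
          vb + ap_kernel(u, dv_up, r_up, dv_dn, r_dn, t_dn),
          c(-8, X1_LOGISTIC * r_up + 3 * r_up), tol = 1e-10)$root
        spike_t <- thr_t + (cross - u1) / 1e3
      }
      sweeps[[si]] <- v
      truth_spikes[[si]] <- list(spike_times_s = spike_t,
                                 threshold_times_s = thr_t,
                                 n_spikes = nspk)
    }
    noisy <- with_cfg_seed(cfg, lapply(sweeps, function(v)
      v + membrane_noise(length(v), noise_sd, fs)))
    ss <- structure(list(
      sampling_rate_hz = fs, time_s = t, sweeps = noisy, mode = "cc",
      protocol = list(type = "current_steps", step_pa = step_pa,
                      step_on_s = on, step_dur_s = step_dur_s),
      capacitance_pf = capacitance_pf), class = "patch_sweeps")
    return(list(sweeps = ss,
                truth = list(true_threshold_mv = true_threshold_mv,
                             rheobase_pa = rheobase_pa,
                             per_sweep = truth_spikes)))
  }

  psc_shape <- function(u_s) {
    tr <- psc_rise_ms / 1e3; td <- psc_decay_ms / 1e3
    g <- ifelse(u_s >= 0, exp(-u_s / td) - exp(-u_s / tr), 0)
    tpk <- tr * td / (td - tr) * log(td / tr)
    g / (exp(-tpk / td) - exp(-tpk / tr))
  }

  if (protocol == "opto_psc") {
    dur <- 0.5
    n <- round(dur * fs)
    t <- (seq_len(n) - 1L) * dt
    out <- with_cfg_seed(cfg, {
      success <- stats::runif(n_sweeps) >= failure_prob
      amps <- psc_amplitude_pa * pmax(0.2, 1 + amp_cv * stats::rnorm(n_sweeps))
      sw <- vector("list", n_sweeps)
      for (i in seq_len(n_sweeps)) {
        v <- numeric(n)
        if (success[i]) v <- v - amps[i] * psc_shape(t - stim_time_s)
        sw[[i]] <- v + membrane_noise(n, noise_sd, fs, band_hz = 2e3)
      }
      list(sw = sw, success = success, amps = amps)
    })
    ss <- structure(list(
      sampling_rate_hz = fs, time_s = t, sweeps = out$sw, mode = "vc",
      protocol = list(type = "opto_psc", stim_time_s = stim_time_s),
      capacitance_pf = capacitance_pf), class = "patch_sweeps")
    return(list(sweeps = ss,
                truth = list(success = out$success,
                             amplitudes_pa = ifelse(out$success, out$amps, 0),
                             n_failures = sum(!out$success))))
  }

  # spontaneous
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) * dt
  out <- with_cfg_seed(cfg, {
    n_ev <- stats::rpois(1, psc_rate_hz * (duration_s - 1))
    times <- numeric(0)
    guard <- 0L
    while (length(times) < n_ev && guard < 10000L) {
      cand <- stats::runif(1, 0.5, duration_s - 0.5)
      if (!length(times) || min(abs(times - cand)) > 0.05) times <- c(times, cand)
      guard <- guard + 1L
    }
    times <- sort(times)
    amps <- psc_amplitude_pa * pmax(0.2, 1 + amp_cv * stats::rnorm(length(times)))
    v <- numeric(n)
    for (i in seq_along(times)) {
      win <- which(t >= times[i] & t < times[i] + 0.2)
      v[win] <- v[win] - amps[i] * psc_shape(t[win] - times[i])
    }
    list(v = v + membrane_noise(n, noise_sd, fs, band_hz = 2e3),
         times = times, amps = amps)
  })
  ss <- structure(list(
    sampling_rate_hz = fs, time_s = t, sweeps = list(out$v), mode = "vc",
    protocol = list(type = "spontaneous", duration_s = duration_s),
    capacitance_pf = capacitance_pf), class = "patch_sweeps")
  list(sweeps = ss,
       truth = list(event_times_s = out$times, amplitudes_pa = out$amps))
}
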