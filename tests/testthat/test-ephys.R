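test_that("spike detection finds threshold crossings with a refractory period", {
  expect_length(detect_spikes(rep(-70, 1000), 5e4), 0)

  # two crossings 0.5 ms apart collapse to one detection
  v <- rep(-70, 500)
  v[100:104] <- 10; v[130:134] <- 10  # 0.6 ms apart at 50 kHz
  expect_length(detect_spikes(v, 5e4), 1)
  v[200:204] <- 10                    # 2 ms later: separate spike
  expect_length(detect_spikes(v, 5e4), 2)

  out <- make_patch_sweeps(sim_config(seed = 2), "current_steps",
                           step_pa = c(150), noise_sd = 0.3)
  tr <- out$truth$per_sweep[[1]]
  st <- detect_spikes(out$sweeps$sweeps[[1]], out$sweeps$sampling_rate_hz)
  expect_length(st, tr$n_spikes)
  expect_lt(max(abs(st - tr$spike_times_s)), 0.2e-3)
})

test_that("input-output curves report counts per duration on both axes", {
  out <- make_patch_sweeps(sim_config(seed = 3), "current_steps",
                           step_pa = seq(0, 200, 25), noise_sd = 0.3,
                           capacitance_pf = 100)
  io <- build_io_curve(out$sweeps)
  truth_counts <- vapply(out$truth$per_sweep, `[[`, numeric(1), "n_spikes")
  expect_equal(io$n_spikes, truth_counts)
  expect_equal(io$ap_freq_hz, truth_counts / 0.5)
  expect_equal(io$current_density_pa_pf, io$current_pa / 100)
  expect_equal(io$current_density_pa_pf[io$current_pa == 200], 2)
  expect_true(all(io$ap_freq_hz[io$current_pa < out$truth$rheobase_pa] == 0))

  nocap <- out$sweeps
  nocap$capacitance_pf <- NA
  expect_warning(io2 <- build_io_curve(nocap), "capacitance")
  expect_true(all(is.na(io2$current_density_pa_pf)))
})

test_that("jerk threshold is exact on a piecewise-cubic onset", {
  fs <- 5e4; dt <- 1 / fs
  t <- seq(0, 0.02, by = dt)
  t0 <- 0.010; v0 <- -55
  v <- v0 + ifelse(t >= t0, 2 * ((t - t0) * 1e3)^3, 0)
  st <- detect_spikes(v, fs)
  th <- voltage_threshold_jerk(v, fs, st[1])
  expect_lt(abs(th$threshold_mv - v0), 0.5)
  expect_lt(abs(th$threshold_time_s - t0), 0.5e-3)
})

test_that("jerk threshold agrees with a finite-difference oracle when noiseless", {
  out <- make_patch_sweeps(sim_config(seed = 5), "current_steps",
                           true_threshold_mv = -44, step_pa = c(150),
                           noise_sd = 0)
  v <- out$sweeps$sweeps[[1]]
  st <- detect_spikes(v, 5e4)
  th <- voltage_threshold_jerk(v, 5e4, st[1])
  o <- oracle_jerk_threshold(v, 2e-5, round(st[1] * 5e4) + 1)
  expect_lt(abs(th$threshold_mv - o), 1)
  expect_lt(abs(th$threshold_mv - (-44)), 1)
})

test_that("jerk threshold recovers generator truth under realistic noise", {
  errs <- vapply(1:20, function(s) {
    out <- make_patch_sweeps(sim_config(seed = s), "current_steps",
                             true_threshold_mv = -42, step_pa = c(150),
                             noise_sd = 0.5)
    cell_voltage_threshold(out$sweeps$sweeps[[1]], 5e4)$threshold_mv + 42
  }, numeric(1))
  expect_lt(abs(mean(errs)), 1)
  expect_lt(sd(errs), 1.5)
})

test_that("a pure-noise window yields a no-threshold error", {
  set.seed(7)
  nz <- rnorm(5000, -70, 0.5)
  expect_error(voltage_threshold_jerk(nz, 5e4, 0.05),
               class = "axq_no_threshold")
})

test_that("evoked PSC amplitude averages the first 15 baseline-subtracted sweeps", {
  out <- make_patch_sweeps(sim_config(seed = 6), "opto_psc", n_sweeps = 15,
                           failure_prob = 0, amp_cv = 0,
                           psc_amplitude_pa = 60, noise_sd = 0)
  amp <- evoked_psc_amplitude(out$sweeps)
  expect_equal(amp$n_used, 15)
  # discrete sampling clips the analytic peak by a sub-per-mille amount
  expect_equal(amp$amplitude_pa, -60, tolerance = 1e-4)

  # identical sweeps: the mean trace equals any single sweep
  expect_equal(amp$mean_trace, out$sweeps$sweeps[[1]] -
                 mean(out$sweeps$sweeps[[1]][out$sweeps$time_s < 0.1]))

  fails <- make_patch_sweeps(sim_config(seed = 6), "opto_psc", n_sweeps = 15,
                             failure_prob = 1, noise_sd = 2)
  a0 <- evoked_psc_amplitude(fails$sweeps)
  # the window extremum of ~100 effective noise samples regularly tops
  # 3 baseline SDs; 5 SDs bounds it while staying far below any PSC
  expect_lt(abs(a0$amplitude_pa), 5 * a0$baseline_sd)
  expect_lt(abs(a0$amplitude_pa), 0.05 * 60)

  short <- make_patch_sweeps(sim_config(seed = 6), "opto_psc", n_sweeps = 10,
                             failure_prob = 0, noise_sd = 1)
  expect_warning(a10 <- evoked_psc_amplitude(short$sweeps), "10")
  expect_equal(a10$n_used, 10)
})

test_that("failure rate reproduces the truth tally and the exclusion rule", {
  big <- make_patch_sweeps(sim_config(seed = 7), "opto_psc", n_sweeps = 20,
                           failure_prob = 0, psc_amplitude_pa = 80,
                           noise_sd = 2)
  fr <- failure_rate(big$sweeps)
  expect_equal(fr$status, "ok")
  expect_equal(fr$failure_rate, 0)

  for (s in 1:20) {
    out <- make_patch_sweeps(sim_config(seed = s), "opto_psc", n_sweeps = 20,
                             failure_prob = 0.4, psc_amplitude_pa = 50,
                             noise_sd = 3)
    fr <- failure_rate(out$sweeps)
    expect_equal(fr$n_failure, out$truth$n_failures)
    expect_equal(fr$n_success + fr$n_failure, 20)
  }

  lone <- make_patch_sweeps(sim_config(seed = 30), "opto_psc", n_sweeps = 20,
                            failure_prob = 1, noise_sd = 2)
  # inject a single success by hand: one sweep gets a large PSC
  lone$sweeps$sweeps[[4]] <- lone$sweeps$sweeps[[4]] -
    80 * exp(-pmax(lone$sweeps$time_s - 0.1, 0) / 0.02) *
    (lone$sweeps$time_s >= 0.1)
  ex <- failure_rate(lone$sweeps)
  expect_equal(ex$status, "excluded")
  expect_true(is.na(ex$failure_rate))
})

test_that("the sliding detection criterion equals a per-lag least-squares fit", {
  set.seed(13)
  fs <- 1e4
  w <- psc_template(fs)
  trace <- rnorm(3000, 0, 4)
  trace[1200:1599] <- trace[1200:1599] + 30 * w
  cb <- cb_criterion(trace, w)
  for (lag in c(1, 57, 1200, 1180, 2500)) {
    o <- oracle_cb_lag(trace, w, lag)
    expect_equal(cb$scale[lag], unname(o["scale"]), tolerance = 1e-8)
    expect_equal(cb$criterion[lag], unname(o["criterion"]), tolerance = 1e-8)
  }
  expect_error(cb_criterion(rnorm(100), w), class = "axq_invalid_parameter")
})

test_that("template matching recovers injected events without spurious hits", {
  rec <- 0L; tru <- 0L; spur <- 0L
  for (s in 1:6) {
    out <- make_patch_sweeps(sim_config(seed = s), "spontaneous",
                             duration_s = 25, psc_rate_hz = 1.2,
                             psc_amplitude_pa = 40, amp_cv = 0,
                             noise_sd = 8, sampling_rate_hz = 1e4)
    det <- detect_spontaneous_pscs(out$sweeps$sweeps[[1]], 1e4)
    tt <- out$truth$event_times_s
    spur <- spur + sum(vapply(det$events$onset_s, function(d)
      min(abs(tt - d)) > 0.005, logical(1)))
    rec <- rec + sum(vapply(tt, function(x)
      any(abs(det$events$onset_s - x) < 0.005), logical(1)))
    tru <- tru + length(tt)
  }
  expect_equal(spur, 0L)
  expect_gte(rec / tru, 29 / 30)

  flat <- detect_spontaneous_pscs(rnorm(5e4, 0, 5), 1e4)
  expect_equal(nrow(flat$events), 0)
  expect_error(detect_spontaneous_pscs(rnorm(100), 1e4),
               class = "axq_invalid_parameter")
})

test_that("the PSC template has the stated kinetics", {
  fs <- 5e4
  w <- psc_template(fs, sign = -1)
  expect_length(w, 0.040 * fs)
  expect_equal(min(w), -1, tolerance = 1e-4)     # unit peak, inward
  expect_true(all(w[seq_len(0.001 * fs)] == 0))  # 1 ms zero baseline
  expect_error(psc_template(fs, rise_ms = 25, decay_ms = 20),
               class = "axq_invalid_parameter")
})
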