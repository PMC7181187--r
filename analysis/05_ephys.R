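#!/usr/bin/env Rscript
# Patch-clamp measurements: input-output curves (pA and pA/pF), the
# jerk-based voltage threshold, evoked GABAergic PSC amplitude over 15
# sweeps, release failure rate, and template-matched spontaneous PSCs.

suppressMessages(library(axoquant))
dir.create("results", showWarnings = FALSE)

## input-output curve from a 10 pA step family
steps <- make_patch_sweeps(sim_config(seed = 3), "current_steps",
                           step_pa = seq(0, 200, 10), capacitance_pf = 80,
                           noise_sd = 0.5)
io <- build_io_curve(steps$sweeps)
write.csv(io, "results/io_curve.csv", row.names = FALSE)
cat(sprintf("I/O: rheobase near %.0f pA (truth %.0f), max rate %.0f Hz at %.1f pA/pF\n",
            min(io$current_pa[io$n_spikes > 0]), steps$truth$rheobase_pa,
            max(io$ap_freq_hz), max(io$current_density_pa_pf)))

## voltage threshold: per-cell median of per-AP jerk estimates
th_rows <- lapply(1:20, function(s) {
  out <- make_patch_sweeps(sim_config(seed = s), "current_steps",
                           true_threshold_mv = -42, step_pa = c(150),
                           noise_sd = 0.5)
  th <- cell_voltage_threshold(out$sweeps$sweeps[[1]], 5e4)
  data.frame(cell = s, threshold_mv = th$threshold_mv,
             n_spikes = th$n_spikes, n_used = th$n_used)
})
th_tab <- do.call(rbind, th_rows)
write.csv(th_tab, "results/voltage_thresholds.csv", row.names = FALSE)
cat(sprintf("Jerk threshold: %.2f +/- %.2f mV across %d cells (truth -42 mV)\n",
            mean(th_tab$threshold_mv), sd(th_tab$threshold_mv), nrow(th_tab)))

## evoked PSCs: amplitude over the first 15 sweeps + failure rate
ev <- make_patch_sweeps(sim_config(seed = 9), "opto_psc", n_sweeps = 20,
                        failure_prob = 0.3, psc_amplitude_pa = 55,
                        noise_sd = 3)
amp <- evoked_psc_amplitude(ev$sweeps)
fr <- failure_rate(ev$sweeps)
cat(sprintf("Evoked PSC: mean-trace peak %.1f pA at %.1f ms post-stimulus\n",
            amp$amplitude_pa, 1e3 * (amp$peak_time_s - 0.1)))
cat(sprintf("Failures: %d/%d sweeps (rate %.2f; truth %.2f; status %s)\n",
            fr$n_failure, 20, fr$failure_rate, ev$truth$n_failures / 20,
            fr$status))
write.csv(data.frame(measure = c("evoked_amplitude_pa", "failure_rate"),
                     value = c(amp$amplitude_pa, fr$failure_rate)),
          "results/evoked_psc.csv", row.names = FALSE)

## spontaneous PSCs by Clements-Bekkers template matching
sp <- make_patch_sweeps(sim_config(seed = 12), "spontaneous",
                        duration_s = 60, psc_rate_hz = 0.8,
                        psc_amplitude_pa = 45, noise_sd = 8,
                        sampling_rate_hz = 1e4)
det <- detect_spontaneous_pscs(sp$sweeps$sweeps[[1]], 1e4)
write.csv(det$events, "results/spontaneous_pscs.csv", row.names = FALSE)
cat(sprintf("Spontaneous: %d events detected / %d injected (criterion > %g); median amplitude %.1f pA\n",
            nrow(det$events), length(sp$truth$event_times_s), det$threshold,
            median(abs(det$events$amplitude))))
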