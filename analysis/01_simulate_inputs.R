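#!/usr/bin/env Rscript
# Generate the synthetic raw inputs used throughout the analysis
# workflow and export them in the pipeline's interchange formats
# (CSV tables, JSON truth sidecars). Every later script regenerates
# what it needs from the same seeds; the exports here document the
# input shapes.

suppressMessages({library(axoquant); library(jsonlite)})
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)

# AIS fluorescence profile (arclength vs intensity)
pr <- make_ais_profile(cfg, length_um = 30, shape = "gaussian", noise_sd = 6)
write.csv(data.frame(position_um = pr$profile$position_um,
                     intensity = pr$profile$intensity),
          "results/simulated/ais_profile.csv", row.names = FALSE)
write_json(pr$truth[c("true_start_um", "true_end_um", "true_length_um")],
           "results/simulated/ais_profile_truth.json", auto_unbox = TRUE)

# ChC field: varicosity table (the format the bouton analyses read)
fld <- make_chc_field(cfg, n_ais = 30, contacted_fraction = 0.5)
write.csv(cbind(fld$field$varicosities, chc_id = 1),
          "results/simulated/varicosities.csv", row.names = FALSE)
write_json(list(contact_map = unname(fld$truth$contact_map),
                contact_fraction = fld$truth$contact_fraction),
           "results/simulated/chc_field_truth.json", auto_unbox = TRUE)

# patch-clamp opto sweeps as long-format time/value CSV
ps <- make_patch_sweeps(cfg, "opto_psc", n_sweeps = 15, failure_prob = 0.3)
sw <- do.call(rbind, lapply(seq_along(ps$sweeps$sweeps), function(i)
  data.frame(sweep = i, time_s = ps$sweeps$time_s,
             current_pa = ps$sweeps$sweeps[[i]])))
write.csv(sw[sw$time_s < 0.2, ], "results/simulated/opto_sweeps.csv",
          row.names = FALSE)

# voltage-imaging repeat series (repeat_id, frame, time_s, F, led_on)
rs <- make_repeat_series(cfg, n_repeats = 10, response_amp = -0.01,
                         noise_sd = 15)
rep_tab <- do.call(rbind, lapply(seq_len(ncol(rs$series$F)), function(r)
  data.frame(repeat_id = r, frame = seq_along(rs$series$time_s),
             time_s = rs$series$time_s, F = rs$series$F[, r],
             led_on = rs$series$led_on)))
write.csv(rep_tab, "results/simulated/repeat_series.csv", row.names = FALSE)

cat("Simulated inputs written under results/simulated/:\n")
cat(sprintf(" - AIS profile: %d samples, true extent %.1f um\n",
            length(pr$profile$position_um), pr$truth$true_length_um))
cat(sprintf(" - ChC field: %d varicosities, %d AIS, contact fraction %.2f\n",
            nrow(fld$field$varicosities), 30, fld$truth$contact_fraction))
cat(sprintf(" - Opto sweeps: %d sweeps, %d true failures\n",
            15, ps$truth$n_failures))
cat(sprintf(" - Repeat series: %d repeats x %d frames at %.0f Hz\n",
            ncol(rs$series$F), nrow(rs$series$F), rs$series$frame_rate))
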