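#!/usr/bin/env Rscript
# Group-level reporting: normality screening (D'Agostino K2), then the
# matching parametric or rank-based comparison with multiple-comparison
# correction, over synthetic per-cell metrics from control and
# activity-manipulated conditions.

suppressMessages({library(axoquant); library(jsonlite)})
dir.create("results", showWarnings = FALSE)

set.seed(77)
tab <- rbind(
  # bouton counts: roughly normal, DREADD condition reduced
  data.frame(condition = "control", metric = "bouton_count",
             value = rnorm(30, 8, 1.6)),
  data.frame(condition = "hM3Dq_CNO", metric = "bouton_count",
             value = rnorm(30, 6, 1.6)),
  # PSC amplitudes: right-skewed, three developmental stages
  data.frame(condition = "P10", metric = "psc_amplitude_pa",
             value = rexp(25, 1 / 15)),
  data.frame(condition = "P14", metric = "psc_amplitude_pa",
             value = rexp(25, 1 / 40)),
  data.frame(condition = "P18", metric = "psc_amplitude_pa",
             value = rexp(25, 1 / 60)))

rep_out <- summarize_groups(tab)
for (m in names(rep_out)) {
  r <- rep_out[[m]]
  cat(sprintf("%s: %s family, %s, p = %.3g (%s at alpha 0.05)\n",
              m, r$family, r$test, r$p.value,
              if (r$significant) "significant" else "not significant"))
  print(r$descriptives, row.names = FALSE, digits = 3)
}

desc <- do.call(rbind, lapply(names(rep_out), function(m)
  cbind(metric = m, rep_out[[m]]$descriptives)))
write.csv(desc, "results/group_descriptives.csv", row.names = FALSE)
write_json(lapply(rep_out, function(r)
  list(family = r$family, test = r$test, p = r$p.value,
       significant = r$significant)),
  "results/group_tests.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/group_descriptives.csv and results/group_tests.json\n")
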