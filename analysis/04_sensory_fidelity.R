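#!/usr/bin/env Rscript
# Sensory-response fidelity with and without the slow oscillation.
#
# Proportional transient inputs (Istim2 = 0.6 * Istim1, 0.06-0.6 nA)
# drive every transient-range (Js, Jo) model, 20 trials per cell, once
# with a 2 Hz sinusoidal background (random phase per trial) and once
# without it.  Per cell: trial-to-trial reliability, stimulus-response
# cross-correlation amplitude and decay, T50, and response amplitude of
# the average ensemble activity.  Writes results/fig7_metrics.csv and
# results/fig8_metrics.csv.

library(mfcircuit)

res7 <- run_protocol(resolve_config("fig7", seed = 1), "results")
res8 <- run_protocol(resolve_config("fig8", seed = 1), "results")

avg <- function(tab) round(colMeans(
  tab[, c("tbt_r", "io_amp", "io_tau_ms", "t50_ms", "resp_amp")],
  na.rm = TRUE), 3)
cat("\nGrid-averaged metrics, with the 2 Hz background:\n")
print(avg(res7$table))
cat("\nGrid-averaged metrics, without the 2 Hz background:\n")
print(avg(res8$table))

# where is fidelity highest?
best <- res7$table[which.max(res7$table$tbt_r), c("Js", "Jo", "tbt_r")]
cat("\nMost reliable cell (with background):\n")
print(best, row.names = FALSE)

cat("\nReading: removing the slow oscillation raises reliability and\n")
cat("input-output correlation across all models while leaving the\n")
cat("temporal metrics nearly unchanged; within the with-background\n")
cat("condition, fidelity is highest at low self-excitation and high\n")
cat("cross-inhibition.\n")
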