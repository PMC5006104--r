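#!/usr/bin/env Rscript
# Paired-comparison workflow on surrogate LFP sessions.
#
# Generates matched control / feedback-modulated synthetic sessions
# (modulated: halved 1-4 Hz slow-oscillation power, shortened evoked
# kernel), computes the input-output metric set per session, and runs
# two-tailed paired t tests across sessions - the same workflow applied
# to in vivo recordings, exercised here on data with known ground truth.
# Writes results/synth_metrics.csv.

library(mfcircuit)

cfg <- resolve_config("synth", seed = 1, n_sessions = 20)
res <- run_protocol(cfg, "results")
tab <- res$table

cat("\nPaired control vs modulated comparisons over",
    nrow(tab), "sessions:\n")
for (m in c("tbt_r", "io_amp", "io_tau_ms", "t50_ms", "low_power")) {
  pc <- paired_comparison(tab[[paste0("ctl_", m)]],
                          tab[[paste0("mod_", m)]])
  cat(sprintf("  %-10s ctl %8.3f  mod %8.3f   t(%d) = %6.2f, p = %.2g\n",
              m, mean(tab[[paste0("ctl_", m)]]),
              mean(tab[[paste0("mod_", m)]]), pc$df, pc$t, pc$p))
}

cat("\nReading: the modulated condition raises reliability and\n")
cat("input-output correlation and shortens the temporal metrics while\n")
cat("suppressing low-frequency power - the direction encoded in the\n")
cat("generator's ground truth, recovered by the analysis pipeline.\n")
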