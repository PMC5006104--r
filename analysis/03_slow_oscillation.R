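#!/usr/bin/env Rscript
# Propagation of a slow (2 Hz) oscillatory input through the circuit.
#
# Both ensembles receive an identical 0.05 nA, 2 Hz sinusoid (fresh
# random phase each trial) on top of background noise; the output is the
# 2 Hz power of the average ensemble activity (S1 + S2)/2.  The power
# map over the transient-range grid shows which coupling combinations
# amplify or attenuate the slow oscillation.  Writes
# results/fig6_metrics.csv.

library(mfcircuit)

cfg <- resolve_config("fig6", seed = 1)
res <- run_protocol(cfg, "results")
tab <- res$table

cat("\n2 Hz output power across the transient-range grid (top cells):\n")
print(head(tab[order(-tab$power_2hz), ], 5), row.names = FALSE)

# figure-exemplar models (per-model background levels as stated)
ex <- data.frame(Js = c(0.35, 0.43, 0.01), Jo = c(0.01, 0.01, 0.35))
ex$power_2hz <- mapply(function(Js, Jo)
  run_slow_osc_protocol(Js, Jo, Io = 0.32, seed = 1), ex$Js, ex$Jo)
cat("\nExemplar models (Io = 0.32 nA):\n")
print(ex, row.names = FALSE)

cat("\nReading: raising self-excitation amplifies the 2 Hz input;\n")
cat("lowering self-excitation and/or raising cross-inhibition\n")
cat("suppresses its propagation.\n")
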