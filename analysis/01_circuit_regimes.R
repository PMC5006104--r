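#!/usr/bin/env Rscript
# Exemplar circuit regimes under the coincident-stimulus series.
#
# Three (Js, Jo) exemplars span the qualitative operating modes of the
# two-ensemble circuit: low/low couplings give transient, independent
# responses; mid/mid give transient responses with strong
# cross-suppression; high/high give sustained winner-take-all dynamics.
# Writes results/fig2_metrics.csv and a manifest.

library(mfcircuit)

cfg <- resolve_config("fig2", seed = 1)
res <- run_protocol(cfg, "results")

cat("\nExemplar regimes (13 coincident stimuli, I1 = 0.5 nA, I2/I1 = 0..4):\n")
print(res$table, row.names = FALSE)

cat("\nReading: the low-coupling model barely notices the competing input\n")
cat("(delta S1 ~ 0); the high-coupling model holds a winner-take-all state\n")
cat("until the competing input overwhelms it (delta S1 > 0.5, crossing\n")
cat("index beyond the matched-input stimulus).\n")
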