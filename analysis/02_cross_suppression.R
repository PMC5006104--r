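#!/usr/bin/env Rscript
# Cross-suppression landscape over the full (Js, Jo) coupling range.
#
# For every cell of the full-range grid (Js 0.01-0.74 nA, Jo 0.01-0.37 nA)
# the 13-stimulus coincident protocol is run and summarized by the
# cross-suppression index (delta S1), the S1-S2 crossing index, and the
# transient/sustained regime label.  Writes results/fig3_metrics.csv.

library(mfcircuit)

cfg <- resolve_config("fig3", seed = 1)
res <- run_protocol(cfg, "results")
tab <- res$table

cat("\nCross-suppression over the full coupling grid:\n")
cat(sprintf("  cells with near-zero suppression (dS1 < 0.1): %d\n",
            sum(tab$delta_s1 < 0.1)))
cat(sprintf("  cells with graded suppression (0.2-0.5):      %d\n",
            sum(tab$delta_s1 >= 0.2 & tab$delta_s1 <= 0.5)))
cat(sprintf("  cells with winner-take-all collapse (> 0.5):  %d\n",
            sum(tab$delta_s1 > 0.5)))
cat(sprintf("  sustained-regime cells:                       %d of %d\n",
            sum(tab$regime == "sustained"), nrow(tab)))

agg <- aggregate(delta_s1 ~ Jo, tab, mean)
cat("\nMean delta S1 by cross-inhibition level:\n")
print(agg, row.names = FALSE)
cat("\nReading: suppression grows with Jo; the sustained regime occupies\n")
cat("the high-Js corner, where crossings shift beyond the matched input.\n")
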