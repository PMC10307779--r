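#!/usr/bin/env Rscript
# Step 2: derive the animals x measures ethogram table.
#
# Applies the formula definitions of the fourteen outcome measures to the
# session-level records: closest-pair trial averaging for withdrawal
# latencies, inverted OLS slopes for the habituation/extinction rates,
# vehicle-normalized drug locomotion, pre-test-subtracted CPP scores, and
# the post-surgery paw and CPP contrasts.

suppressPackageStartupMessages(library(ethopain))

tab <- run_derive("results/cohort", "results/derived", quiet = TRUE)
flags <- attr(tab, "transform_flags")

cat("Measure table written to results/derived/measures.csv\n")
cat("  animals:", nrow(tab), "  measures:", ncol(tab) - 1, "\n")
tf <- names(flags)[flags]
cat("  square-root transform applied to:",
    if (length(tf)) paste(tf, collapse = ", ") else "none", "\n\n")
cat("Cohort means (pre-surgery measures):\n")
for (m in pre_measure_names())
  cat(sprintf("  %-35s %10.2f\n", m, mean(tab[[m]], na.rm = TRUE)))
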