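#!/usr/bin/env Rscript
# Step 1: simulate the default synthetic cohort.
#
# Fifteen animals traverse the five study phases: four reflex-pain sessions
# (days 6-9), a place-preference pre-test (day 10), four days of paired
# vehicle/oxycodone conditioning (days 13-16), seven extinction tests (days
# 17-51), a balanced sham/CCI surgery, three post-surgery reflex sessions
# (days 63-65) and a final place test (day 66).  Latent per-animal traits
# carry the correlation structure the later analyses interrogate.

suppressPackageStartupMessages(library(ethopain))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 20230628L

cfg <- generator_config(seed = seed)
study <- run_simulate(cfg, "results/cohort", quiet = TRUE)

cat("Simulated cohort written to results/cohort/ (seed ", seed, ")\n", sep = "")
print(study)
cat("\nPlanted headline correlations (latent traits):\n")
R <- cfg$latent_corr
cat(sprintf("  basal latency  vs sensitization slope: %+.2f\n",
            R["basal_latency", "sensitization_slope"]))
cat(sprintf("  basal loco     vs loco habituation:    %+.2f\n",
            R["basal_loco", "loco_habituation"]))
cat(sprintf("  sensitization  vs extinction rate:     %+.2f\n",
            R["sensitization_slope", "extinction_rate"]))
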