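#!/usr/bin/env Rscript
# Step 3: the group-level statistical battery.
#
# Session-course within-subjects ANOVAs, one-sample t tests of the slope
# measures against zero, paired pre/post-conditioning CPP comparisons and
# sham-vs-CCI contrasts on the post-surgery measures (Mann-Whitney wherever
# a group fails the Shapiro-Wilk normality check), plus the dose
# translation.  All p values are two-tailed and uncorrected.

suppressPackageStartupMessages(library(ethopain))

study <- read_study("results/cohort")
measures <- utils::read.csv("results/derived/measures.csv",
                            check.names = FALSE)
battery <- run_report(study, measures, out_dir = "results/stats",
                      quiet = TRUE)

cat("Statistical battery written to results/stats/group_stats.csv\n\n")
fmt <- function(r) {
  df <- if (is.na(r$df1)) "" else if (is.na(r$df2))
    sprintf("(%g)", r$df1) else sprintf("(%g,%g)", r$df1, r$df2)
  sprintf("  %-28s %-40s %s%s = %8.3f  p = %.4f",
          r$test, r$measure, r$statistic_name, df, r$statistic, r$p)
}
for (i in seq_len(nrow(battery))) cat(fmt(battery[i, ]), "\n")
cat(sprintf("\n0.56 mg/kg in rat ~ %.1f mg human-equivalent dose (70 kg, BSA divisor 6.2)\n",
            attr(battery, "human_equivalent_dose_mg")))
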