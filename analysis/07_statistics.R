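#!/usr/bin/env Rscript
# Stage 7 — cohort-level brain-behaviour statistics.
#
# Per-subject Q-slope and early-Q features, then the correlation battery:
# one-sample t on Q-slope betas, Pearson r of Q-slope and early Q against
# learning rate and habit strength, paired t of compatible vs incompatible
# drift, and a median split by learning rate with group mean Q curves.
# Habit outliers (3 SD) are excluded before all statistics.

suppressMessages(library(segdyn))

cohort <- readRDS("results/cohort/cohort_cache.rds")
mod <- readRDS("results/modularity_cache.rds")
beh <- read.csv("results/behavior_summaries.csv")

feats <- t(vapply(seq_len(nrow(mod$q_mat)), function(i) {
  f <- trajectory_features(mod$q_mat[i, ], mod$trial_counts)
  c(f$slope, f$early)
}, numeric(2)))
summaries <- data.frame(subject_id = rownames(mod$q_mat),
                        q_slope = feats[, 1], early_q = feats[, 2])
summaries <- merge(summaries, beh, by = "subject_id")
retained <- summaries[!summaries$habit_outlier, ]
write.csv(summaries, "results/subject_summaries.csv", row.names = FALSE)

keep <- rownames(mod$q_mat) %in% retained$subject_id
st <- cohort_statistics(retained, q_curves = mod$q_mat[keep, , drop = FALSE])
jsonlite::write_json(unclass(st), "results/stats_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("n = %d retained subjects\n", st$n))
cat(sprintf("Q-slope one-sample t(%d) = %.2f, p = %.2e (mean slope %.4f)\n",
            st$q_slope_t$df, st$q_slope_t$t, st$q_slope_t$p,
            st$q_slope_t$mean))
cat(sprintf("r(Q-slope, learning rate) = %.3f (p = %.3f)\n",
            st$r_qslope_learning$r, st$r_qslope_learning$p))
cat(sprintf("r(Q-slope, habit strength) = %.3f (p = %.3f)\n",
            st$r_qslope_habit$r, st$r_qslope_habit$p))
cat(sprintf("r(early Q, learning rate) = %.3f (one-tailed p = %.3f)\n",
            st$r_earlyq_learning$r, st$r_earlyq_learning$p))
cat(sprintf("paired t (compatible vs incompatible drift): t(%d) = %.2f, p = %.3f\n",
            st$drift_paired_t$df, st$drift_paired_t$t, st$drift_paired_t$p))
gt <- cohort$ground_truth[cohort$ground_truth$subject_id %in%
                            retained$subject_id, ]
cat(sprintf("realized ground-truth corr(rate, exponent) = %.3f\n",
            cor(gt$transition_rate, gt$learning_exponent)))
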