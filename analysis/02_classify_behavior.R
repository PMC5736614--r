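#!/usr/bin/env Rscript
# Classify every feedback event of the simulated sessions by informative value
# and valence, compute learning performance, and summarise a small simulated
# cohort's counts per category.

library(feedlearn)

dir.create("results", showWarnings = FALSE)
set.seed(20260102)

logs <- list.files("results/sessions", pattern = "_trials\\.csv$",
                   full.names = TRUE)
if (length(logs) == 0) stop("run analysis/01_simulate_task.R first")

classified <- lapply(logs, function(f) classify_session(read_trials(f)))
names(classified) <- basename(logs)

for (f in seq_along(logs)) {
  out <- sub("_trials.csv", "_labeled.csv", logs[f], fixed = TRUE)
  write.csv(classified[[f]]$trials, out, row.names = FALSE)
}

summary_tab <- count_summary(classified)
summary_tab$session <- basename(logs)
write.csv(summary_tab, "results/classification_summary.csv", row.names = FALSE)
cat("Per-session classification summary:\n")
print(summary_tab, row.names = FALSE)

# calibration report over a simulated wave-1 cohort: mean trial counts per
# category and the wave-wise 3-SD outlier rule
cat("\nSimulating a 60-agent wave-1 cohort for the count calibration...\n")
cohort_cls <- lapply(runif(60, 8, 25), function(a)
  classify_session(simulate_participant(a, config = task_config_wave(1))))
counts <- count_summary(cohort_cls)
cat(sprintf("learning trials: mean %.2f (SD %.2f); application: mean %.2f (SD %.2f)\n",
            mean(counts$learning), sd(counts$learning),
            mean(counts$application), sd(counts$application)))
cat(sprintf("learning performance: mean %.2f (SD %.2f)\n",
            mean(counts$performance), sd(counts$performance)))

perf <- data.frame(wave = 1, performance = counts$performance)
cat("outliers by the wave-wise 3-SD rule:", sum(flag_outliers(perf)), "\n")
write.csv(counts, "results/cohort_counts.csv", row.names = FALSE)
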