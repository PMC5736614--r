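#!/usr/bin/env Rscript
# Simulate feedback-learning sessions for agents across the age range and
# write trial logs plus BIDS-style feedback-event timelines.

library(feedlearn)

dir.create("results/sessions", showWarnings = FALSE, recursive = TRUE)
set.seed(20260101)

ages <- c(9, 13, 17, 21, 25)
profile <- developmental_profile()

cat("Simulating wave-1 sessions (15 sequences, max 180 trials) at ages:",
    paste(ages, collapse = ", "), "\n")
for (age in ages) {
  trials <- simulate_participant(age, profile, task_config_wave(1))
  stem <- sprintf("results/sessions/age%02d", age)
  write_trials(trials, paste0(stem, "_trials.csv"))
  write_events(trials, file = paste0(stem, "_events.tsv"))
  cat(sprintf("  age %2d: %3d trials, %2d sequences\n",
              age, nrow(trials), length(unique(trials$sequence_id))))
}

# the design arithmetic: a learner that never sorts correctly exhausts the cap
n1 <- nrow(run_session(policy_never_correct, task_config_wave(1), seed = 1))
n3 <- nrow(run_session(policy_never_correct, task_config_wave(3), seed = 1))
cat(sprintf("\nTrial budget check: wave-1 cap %d (15 x 12), wave-3 cap %d (10 x 12)\n",
            n1, n3))
stopifnot(n1 == 180, n3 == 120)
cat("Session files written under results/sessions/\n")
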