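#!/usr/bin/env Rscript
# Fit the no-age / linear / quadratic random-intercept ladder per ROI and
# contrast, estimate peak ages for concave quadratics, and compute ICCs.

library(feedlearn)

rows <- read_cohort_rows("results/cohort.csv")
dir.create("results", showWarnings = FALSE)

strata <- unique(rows[, c("roi", "contrast")])
out <- list(); curves <- list()
for (k in seq_len(nrow(strata))) {
  sub <- rows[rows$roi == strata$roi[k] & rows$contrast == strata$contrast[k], ]
  lad <- compare_ladder(sub, "activity")
  row <- data.frame(roi = strata$roi[k], contrast = strata$contrast[k],
                    aic0 = lad$table$AIC[1], aic1 = lad$table$AIC[2],
                    aic2 = lad$table$AIC[3],
                    lrt_p_01 = lad$table$lrt_p[2],
                    lrt_p_12 = lad$table$lrt_p[3],
                    selected = lad$selected,
                    peak = NA_real_, peak_lo = NA_real_, peak_hi = NA_real_)
  if (identical(lad$selected, 2L)) {
    pk <- peak_age(lad$fits[[3]], seed = 1)
    if (pk$valid) {
      row$peak <- pk$peak; row$peak_lo <- pk$ci[1]; row$peak_hi <- pk$ci[2]
    }
  }
  sel_fit <- lad$fits[[lad$selected + 1L]]
  cv <- predict_trajectory(sel_fit, seq(8, 29, by = 0.25))
  cv$roi <- strata$roi[k]; cv$contrast <- strata$contrast[k]
  curves[[k]] <- cv
  out[[k]] <- row
}
ladder_tab <- do.call(rbind, out)
write.csv(ladder_tab, "results/trajectory_ladder.csv", row.names = FALSE)
write.csv(do.call(rbind, curves), "results/trajectory_curves.csv",
          row.names = FALSE)

cat("Age-ladder selection per stratum (0 = no age, 1 = linear, 2 = quadratic):\n")
print(ladder_tab[, c("roi", "contrast", "selected", "peak")], row.names = FALSE)

perf <- unique(rows[, c("subject_id", "wave", "age")])
perf$performance <- rows$performance[match(paste(perf$subject_id, perf$wave),
                                           paste(rows$subject_id, rows$wave))]
cat(sprintf("\nlearning-performance ICC: %.3f\n", icc(perf, "performance")))
iccs <- sapply(seq_len(nrow(strata)), function(k) {
  sub <- rows[rows$roi == strata$roi[k] & rows$contrast == strata$contrast[k], ]
  icc(sub, "activity")
})
cat(sprintf("ROI activity ICCs: %.3f-%.3f (median %.3f)\n",
            min(iccs), max(iccs), median(iccs)))
cat("Tables written to results/trajectory_ladder.csv and trajectory_curves.csv\n")
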