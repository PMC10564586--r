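#!/usr/bin/env Rscript
# Fits all 32 sex x age x indicator survey series, regenerates the model
# tables (parameters, fitted 2000-2020, forecasts 2025/2030, growth rows),
# compares every cell with the published tables, and writes the abstract's
# age-averaged growth summaries.

library(greygrowth)
dir.create("results", showWarnings = FALSE)

rt <- reproduce_tables()

write.csv(rt$cells, "results/table_cells_comparison.csv", row.names = FALSE)
write.csv(rt$summary, "results/table_match_summary.csv", row.names = FALSE)
write.csv(rt$errata, "results/printed_errata.csv", row.names = FALSE)

anthro <- rt$cells[!rt$cells$indicator %in%
                     c("obesity_rate", "overweight_rate"), ]
cat(sprintf("anthropometry cells compared: %d, matching at 1 d.p.: %.1f%%\n",
            sum(!is.na(anthro$printed)),
            100 * mean(anthro$match, na.rm = TRUE)))
m2030 <- anthro[anthro$field == "2030", ]
cat(sprintf("2030 cells matching: %.0f%% (known mismatch: the source prints\n",
            100 * mean(m2030$match, na.rm = TRUE)))
cat("values ~0.3-0.5 below the pure exponential extrapolation)\n\n")

# age-averaged growth summaries (rounded-first deltas over ages 3-6)
summaries <- NULL
for (ind in c("height", "weight", "chest_circumference", "bmi"))
  for (sx in c("boys", "girls")) {
    recs <- lapply(3:6, function(a)
      fit_indicator_series(cnpfs_means(), ind, sx, a))
    for (per in c("2020-2000", "2030-2020")) {
      cs <- cohort_summary(recs, per)
      summaries <- rbind(summaries, data.frame(
        indicator = ind, sex = sx, period = per,
        mean_delta = cs$mean_delta, annualized_pct = cs$annualized_pct))
    }
  }
write.csv(summaries, "results/cohort_summaries.csv", row.names = FALSE)
print(summaries, row.names = FALSE)
cat("\nboys 2000-2020: height +3.6 cm (0.16 %/yr), weight +1.8 kg —\n")
cat("the headline secular-trend figures of the study\n")
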