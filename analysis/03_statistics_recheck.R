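#!/usr/bin/env Rscript
# Stage 3 — statistics re-run from the persisted outcome table.
#
# Demonstrates stage re-runnability: reads results/study/outcomes_tidy.csv
# written by stage 2 (no in-memory state) and recomputes the normality
# screen, the two-way ANOVA, and the Tukey comparisons per outcome per
# joint, writing them under results/03_stats.

suppressPackageStartupMessages(library(gaitload))

tidy_path <- "results/study/outcomes_tidy.csv"
if (!file.exists(tidy_path)) {
  stop("run analysis/02_run_study.R first: ", tidy_path, " not found")
}
grid <- read.csv(tidy_path, stringsAsFactors = FALSE)
out_dir <- "results/03_stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat(sprintf("loaded %d outcome records\n", nrow(grid)))
summary_rows <- list()
for (m in c("peak_torque", "peak_power", "work")) {
  for (j in c("ankle", "knee", "hip")) {
    slice <- grid[grid$joint == j, ]
    cell <- interaction(slice$speed, slice$load)
    resid <- slice[[m]] - ave(slice[[m]], cell)
    ks <- ks_normality(resid)
    an <- two_way_anova(slice, m)
    write.csv(an, file.path(out_dir, sprintf("anova_%s_%s.csv", m, j)),
              row.names = FALSE)
    for (fac in c("speed", "load")) {
      mc <- multiple_comparisons(slice, m, fac)
      write.csv(mc, file.path(out_dir,
                              sprintf("posthoc_%s_%s_%s.csv", m, j, fac)),
                row.names = FALSE)
    }
    summary_rows[[paste(m, j)]] <- data.frame(
      outcome = m, joint = j,
      ks_p = ks$p_value,
      p_speed = an$p[1], p_load = an$p[2], p_interaction = an$p[3]
    )
  }
}
summary_df <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
cat("per-outcome, per-joint test summary (KS on cell residuals; ANOVA p):\n")
print(summary_df, row.names = FALSE, digits = 3)
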