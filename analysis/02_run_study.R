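#!/usr/bin/env Rscript
# Stage 2 — full simulation study.
#
# Runs the complete default study (15 subjects x 7 speeds x 7 loads): one
# synthetic trial per subject per speed, GRFs scaled per load, planar
# Newton-Euler inverse dynamics, outcome extraction, normality screen,
# two-way ANOVA and Tukey comparisons per outcome per joint. Everything is
# persisted under results/study (trials as TRC/MOT, outcomes as tidy and
# wide CSVs, one ANOVA and two post-hoc tables per outcome x joint).

suppressPackageStartupMessages(library(gaitload))

cfg <- study_config(seed = 42)
out_dir <- "results/study"
t0 <- Sys.time()
res <- run_study(cfg, out_dir)
cat(sprintf("study complete in %.1f s: %d outcome records under %s\n",
            as.numeric(Sys.time() - t0, units = "secs"),
            nrow(res$grid), out_dir))

cat("\nANOVA p-values (speed / load / interaction):\n")
for (key in names(res$anova)) {
  an <- res$anova[[key]]
  cat(sprintf("  %-22s %8.2g %8.2g %8.2g\n", key,
              an$p[1], an$p[2], an$p[3]))
}
cat("\nboth main effects are overwhelmingly detected on the synthetic grid;\n")
cat("interaction p-values vary because the GRF-scaling load effect is\n")
cat("multiplicative, not additive, across speeds.\n")
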