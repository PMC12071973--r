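#!/usr/bin/env Rscript

# Stage 4: cohort comparisons.
#
# One-tailed pooled t-test (later cohort hypothesized higher) for each of the
# three matrix tracks, writing full-precision JSON and rounded text reports
# under results/compare_<metric>/.

suppressPackageStartupMessages(library(carematrix))

groups <- c("2017-2018", "2022-2023")
for (metric in c("swa", "pba", "combined")) {
  res <- run_compare("results/scores.csv", metric = metric, groups = groups,
                     direction = "greater",
                     out_dir = file.path("results", paste0("compare_", metric)))
  cmp <- res$comparison
  cat(sprintf(
    "%-8s %s mean %.2f vs %s mean %.2f: t = %.2f, df = %d, one-tailed p = %.2g (%s)\n",
    metric, groups[1], cmp$mean_a, groups[2], cmp$mean_b, cmp$t_statistic,
    cmp$df, cmp$p_one_tailed,
    if (cmp$significant) "significant" else "not significant"))
}
cat("wrote: results/compare_{swa,pba,combined}/\n")
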