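#!/usr/bin/env Rscript

# Step 4: two-way (treatment x sex) ANOVAs.
#
# For each of the ten metrics: Type III F tests for the two main effects and
# their interaction on complete cases (birds with excluded networks drop out
# of the network-metric fits only), plus the mean +/- SEM cell summary
# behind bar plots.

suppressPackageStartupMessages(library(songsyntax))

metrics <- read.csv("results/metrics.csv", stringsAsFactors = FALSE)
at <- anova_table(metrics)
cs <- summarize_cells(metrics)
write.csv(at, "results/anova.csv", row.names = FALSE)
write.csv(cs, "results/cell_summary.csv", row.names = FALSE)

alpha <- 0.05
sex <- at[at$effect == "sex", ]
cat("sex effects (alpha = 0.05):\n")
for (i in seq_len(nrow(sex))) {
  cat(sprintf("  %-26s F(%d,%d) = %8.3f  p = %.4g %s\n",
              sex$metric[i], sex$df1[i], sex$df2[i], sex$F[i], sex$p[i],
              if (sex$p[i] < alpha) "*" else ""))
}
trt <- at[at$effect == "treatment", ]
cat(sprintf("treatment effects significant for %d of %d metrics\n",
            sum(trt$p < alpha), nrow(trt)))
int <- at[at$effect == "interaction", ]
cat(sprintf("interaction significant for %d of %d metrics\n",
            sum(int$p < alpha), nrow(int)))
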