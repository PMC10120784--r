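#!/usr/bin/env Rscript

# Step 5: mean +/- SEM bar figures for the diversity and network metrics,
# one panel per metric, split by treatment and sex.

suppressPackageStartupMessages({
  library(songsyntax)
  library(ggplot2)
})

cs <- read.csv("results/cell_summary.csv", stringsAsFactors = FALSE)
cs$group <- interaction(cs$sex, cs$treatment, sep = " / ")

p <- ggplot(cs, aes(x = sex, y = mean, fill = treatment)) +
  geom_col(position = position_dodge(0.9), colour = "black", width = 0.8) +
  geom_errorbar(aes(ymin = mean - sem, ymax = mean + sem),
                position = position_dodge(0.9), width = 0.25) +
  facet_wrap(~metric, scales = "free_y", ncol = 4) +
  scale_fill_manual(values = c("T" = "grey60", "T+E2" = "white")) +
  labs(y = "mean ± SEM", x = NULL, fill = NULL) +
  theme_classic(base_size = 10)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
ggsave("results/figures/metric_panels.svg", p, width = 10, height = 6,
       device = function(filename, ...) grDevices::svg(filename, ...))
cat("wrote results/figures/metric_panels.svg\n")
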