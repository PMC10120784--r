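#!/usr/bin/env Rscript

# Step 3: syllable-transition networks.
#
# Builds each bird's first-order transition network from the concatenated
# 30-song syllable string (song breaks ignored), flags networks with three
# or fewer syllable types, and exports example diagrams for one male and one
# female (node size ~ syllable-type usage, edge darkness ~ transition count).

suppressPackageStartupMessages(library(songsyntax))

corpus <- read_corpus_csv("results/data/corpus.csv")
birds <- lapply(corpus_to_birds(corpus), first_n_songs, n = 30L)
names(birds) <- vapply(birds, `[[`, "", "bird_id")

nets <- lapply(birds, function(b) build_network(song_strings(b)))
ex <- exclude_small(nets)
write.csv(ex$exclusion_log, "results/network_exclusions.csv", row.names = FALSE)

net_metrics <- do.call(rbind, lapply(nets, network_metrics))
net_metrics <- cbind(bird_id = names(nets), net_metrics)
write.csv(net_metrics, "results/network_metrics.csv", row.names = FALSE)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
sexes <- vapply(birds, `[[`, "", "sex")
for (sx in c("male", "female")) {
  id <- names(birds)[sexes == sx][1]
  export_diagram(nets[[id]], sprintf("results/figures/network_%s.svg", sx),
                 seed = 7, main = sprintf("%s (%s)", id, sx))
}

cat(sprintf("built %d networks; %d excluded (<= 3 syllable types)\n",
            length(nets), sum(ex$exclusion_log$excluded)))
print(aggregate(cbind(path_length, density) ~ sexes,
                cbind(net_metrics, sexes = sexes), function(x) mean(x, na.rm = TRUE)),
      digits = 3)
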