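#!/usr/bin/env Rscript

# Step 2: per-bird diversity metrics.
#
# Reads the corpus written by 01_simulate.R, keeps each bird's first 30
# songs, and computes the eight diversity metrics (both repertoires, per-song
# counts and rates, SVI, mean Levenshtein distance between successive songs)
# plus the two transition-network metrics.

suppressPackageStartupMessages(library(songsyntax))

corpus <- read_corpus_csv("results/data/corpus.csv")
birds <- corpus_to_birds(corpus)
birds <- lapply(birds, first_n_songs, n = 30L)

metrics <- metric_table(birds)
write.csv(metrics, "results/metrics.csv", row.names = FALSE)

cat(sprintf("computed 10 metrics for %d birds (%d networks excluded as <= 3 types)\n",
            nrow(metrics), sum(metrics$network_excluded)))
print(aggregate(cbind(syllable_type_repertoire, song_type_repertoire, svi,
                      levenshtein_mean) ~ sex, metrics, mean), digits = 3)
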