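#!/usr/bin/env Rscript

# Step 1: simulate the study cohort.
#
# 2 sexes x 2 steroid treatments (T, T+E2), 7 birds per cell, 30 songs per
# bird. Male-typed birds: ~12 syllable types, near-deterministic transitions,
# short trills. Female-typed birds: ~5 types, variable transitions, long
# trills. Song length and timing are matched across sexes so only diversity
# and syntax, not output, carry the sex signal.

suppressPackageStartupMessages(library(songsyntax))

seed <- 101L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_spec(seed = seed))
write_corpus_csv(cohort$corpus, "results/data/corpus.csv")
write.csv(cohort$truth, "results/data/truth.csv", row.names = FALSE)

# also emit one TextGrid per cell's first bird, exercising the PRAAT reader
dir.create("results/data/textgrids", showWarnings = FALSE)
for (b in cohort$birds[match(unique(paste(cohort$truth$sex, cohort$truth$treatment)),
                             paste(cohort$truth$sex, cohort$truth$treatment))]) {
  write_textgrid(do.call(rbind, b$songs),
                 sprintf("results/data/textgrids/%s.TextGrid", b$bird_id))
}

cat(sprintf("simulated %d birds, %d songs, %d syllables (seed %d)\n",
            nrow(cohort$truth), length(unique(paste(cohort$corpus$bird_id,
                                                    cohort$corpus$song_index))),
            nrow(cohort$corpus), seed))
cat("true repertoire by sex:\n")
print(tapply(cohort$truth$true_repertoire, cohort$truth$sex, mean))
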