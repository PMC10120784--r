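Package: songsyntax
Title: Song Diversity and Syllable Syntax Analysis for Steroid-Treated Canaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify song diversity and syllable syntax from
    per-syllable annotations of birdsong, developed around testosterone-induced
    song in male and female canaries. Reads PRAAT TextGrid annotations or a
    flat CSV dialect, segments syllable streams into songs by a
    silence/duration rule, computes eight classical diversity metrics
    (repertoire sizes, per-song syllable counts and rates, syllable
    versatility index, Levenshtein distance between successive songs), builds
    per-bird first-order syllable-transition networks with average minimum
    path length and density, and fits two-way (treatment x sex) Type III
    ANOVAs per metric. A first-order Markov song simulator generates
    sex-typed synthetic cohorts for testing and power experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    car,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
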