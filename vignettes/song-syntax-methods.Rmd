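---
title: "Quantifying song diversity and syllable syntax: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying song diversity and syllable syntax: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songsyntax)
```

## The problem

Male and female canaries can both be brought to sing at high rates by
testosterone (T) or testosterone-plus-estradiol (T+E2) implants, but the
songs they produce are not equivalent. The differences are not in sheer
output — song duration, syllable counts and delivery rates match — but in
*which* syllables are used and *how* they are strung together. `songsyntax`
implements the analysis chain needed to quantify that distinction from
per-syllable annotations: song segmentation, a panel of eight diversity
metrics, first-order syllable-transition networks, and a two-way
(treatment × sex) ANOVA layer. A first-order Markov song simulator generates
sex-typed cohorts so every stage, and the expected direction of every sex
contrast, can be tested without access to recordings.

The unit of input is the annotated syllable: an interval (onset, offset, in
seconds) labelled with a syllable-type identifier, as produced by manual
annotation in PRAAT. Syllable classification itself is out of scope; the
annotation is taken as ground truth, labels are whitespace-stripped and
case-sensitive, and no fuzzy label merging is attempted.

## Song segmentation

A *song* is a vocalization at least 1 s long bounded by at least 0.4 s of
silence. `segment_songs()` applies this to a sorted syllable stream: silence
gaps are measured offset → next onset (the annotation carries no other
boundaries), maximal runs whose internal gaps are all shorter than
`min_silence` form candidate bouts, and bouts spanning at least
`min_duration` (first onset to last offset) become songs. A gap of exactly
`min_silence` splits: 0.4 s of silence is a valid separator under the
"at least 0.4 s" reading. Sub-threshold bouts are not silently dropped — they
are returned in a `discarded` attribute so that every input token is
accounted for (a property the test suite checks). Analysis uses each bird's
first 30 songs (`first_n_songs()`); birds with fewer are flagged
`underfilled`.

## The diversity panel

Eight per-bird variables, computed from the 30 `song_strings()`:

* **Syllable type repertoire** — distinct syllable types across all songs.
* **Song type repertoire** — distinct song types (see below).
* **Syllables per song**, **syllable types per song** — within-song counts,
  averaged over songs with equal weight.
* **Syllables per second**, **syllable types per second** — within-song
  counts divided by that song's own duration, then averaged.
* **SVI** (syllable versatility index) — per song, distinct types divided by
  token count, in (0, 1]; averaged. 1 means no syllable is repeated within a
  song; heavily trilled song pushes SVI toward 1/length.
* **Levenshtein distance** — mean over the 29 consecutive song pairs, in
  recording order, of the minimum number of single-token insertions,
  deletions and substitutions converting one syllable sequence into the
  next. Distances operate on whole syllable-type tokens, never on the
  characters of label text, and are reported as raw counts; a
  length-normalized variant (`normalize = TRUE`) exists for cross-study
  comparison but is not used in the default pipeline, since raw minimum edit
  counts are the canonical definition.

Per-song-then-average is used for all rate-like quantities (rather than
pooling totals across songs) because the per-bird value is conceptually "the
average of the first 30 songs"; offering a single canonical estimator avoids
silent divergence between analyses.

**What is a song type?** Two conventions are implemented. `"type_set"`
(default) types a song by its unordered set of syllable types: two
renditions built from the same material are the same type. `"sequence"`
uses exact ordered label-sequence identity — the strictest reproducible
reading. For songs of many dozens of syllables, however, essentially every
rendition is sequence-unique, so the sequence count saturates at the number
of sampled songs for every bird and carries no information (on the default
synthetic cohort it is exactly 30 everywhere, which even leaves the ANOVA
undefined for zero residual variance). Content-based typing is therefore the
default; the mode is a visible argument throughout.

## Transition networks

`build_network()` concatenates the 30 songs, in temporal order, into one
token string and counts every adjacent ordered pair as a directed
first-order transition. Song breaks are ignored by default so that the pair
straddling a boundary is counted too — small corpora otherwise fragment into
disconnected networks; `respect_song_breaks = TRUE` inverts this for
sensitivity analysis. Self-transitions (trills) are retained in the directed
edge counts, where they matter for visualization.

The two metrics are computed on the *undirected simple view*: direction
collapsed, multi-edges merged, self-loops removed, counts ignored (edge
presence is what the definitions count):

* **Average minimum path length** — mean breadth-first shortest-path length
  over all unordered node pairs that are mutually reachable; unreachable
  pairs are omitted from numerator and denominator (the conventional
  unconnected-pairs treatment of "ignoring dead ends"). Higher values mean
  more fixed, linear syntax.
* **Density** — observed edges divided by the n(n−1)/2 possible transitions
  between distinct types. Self-loops are excluded from both numerator and
  denominator: a trill repetition is not a transition between two types, and
  "possible transitions given network size" reads most naturally as the
  simple-graph denominator. Higher density means more flexible sequencing.

Networks with three or fewer syllable types are excluded from metric
analysis (`network_metrics()` reports `NA`, `exclude_small()` logs the
decision): with so few nodes both metrics are dominated by the node count
itself. Degenerate cases are reported as missing rather than invented:
density is undefined below two nodes, path length is `NA` when no pair is
reachable (e.g. a pure one-type trill corpus).

Both metrics are invariant under relabeling of syllable types, and path
length is checked exhaustively against an independent Floyd–Warshall
implementation for all graphs on up to 5 nodes plus 1000 random graphs on
6–8 nodes.

## The ANOVA layer

`fit_two_way_anova()` fits `value ~ treatment * sex` on complete cases with
sum-to-zero contrasts and Type III sums of squares (via `car::Anova`),
reporting F, df and p for the two main effects and the interaction at
α = 0.05, with no multiple-testing correction. Type III with sum-to-zero
coding is the decomposition that remains interpretable under mildly
unbalanced cell counts (real cohorts of this kind end up with, say, 15 males
vs 13 females), and it coincides with the sequential decomposition on
balanced data — asserted in the tests, along with a textbook
sums-of-squares oracle and a 2000-replicate null calibration of the type-I
error rate.

Missingness is handled per metric: birds whose networks were excluded drop
out of the network-metric fits only, so with a full 2 × 2 design the error
df is `n − 4` for the diversity metrics and shrinks by exactly the number of
excluded birds for the network metrics (28 birds with 2 exclusions gives the
24 vs 22 pattern; the tests construct exactly this scenario). Empty cells
and zero residual variance raise errors naming the problem rather than
returning nonsense. `summarize_cells()` emits the mean ± SEM table behind
bar plots, with SEM undefined (`NA`) for singleton cells.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical* structure the analysis
assumes, not canary phonology. Each bird gets:

* a repertoire size drawn from a normal around the profile mean (SD
  `max(0.75, 0.15·mean)`, floored at 1 type, rounded) — individual
  variability is marked in steroid-induced song, and without it the
  repertoire metric would be degenerate within cells;
* a first-order transition matrix whose rows put `1 − 1/trill_length_mean`
  on the self-transition (geometric trill runs of that mean length) and
  spread the rest as a `transition_determinism`-weighted mixture of a
  uniform distribution and a one-hot distribution on a randomly chosen
  preferred successor — determinism 0 is maximally flexible, 1 is a fixed
  cycle;
* 30 songs of Poisson(69)-many syllables (the scale of real steroid-induced
  cohorts: ~57,900 syllables across 840 songs), placed on a timeline with
  ~0.10 s syllables, 0.05 s intra-song gaps and ≥ 0.5 s inter-song gaps so
  that segmentation at the 1 s / 0.4 s rule recovers the songs exactly
  (round-tripped in the tests).

The default sex profiles encode the two regimes the analysis is meant to
distinguish: males with `repertoire 12, determinism 0.9, trill mean 3`
(large repertoire, fixed transition patterns, frequent short trills) and
females with `repertoire 5, determinism 0.3, trill mean 6` (small
repertoire, flexible transitions, long repeats of the same types). Song
length and timing are identical across profiles, so syllables/song and
syllables/sec carry no sex signal by construction — matching the real
finding that output measures do not differ. The treatment effect defaults
to null (a multiplier on the T+E2 repertoire is available for power
experiments), and all randomness flows through the single cohort seed; a
fixed seed regenerates the corpus byte-identically.

Across 20 seeded cohorts the full pipeline yields significant sex effects in
the expected direction for both repertoires, types/song, types/sec, SVI and
path length (male > female) and density (female > male), with no systematic
effect on syllables/song or syllables/sec — the acceptance suite computes
exactly these counts.

## Known limitations

* **Levenshtein under first-order generation.** The generator is
  deliberately a plain first-order Markov chain, the exact conjugate of the
  first-order network analysis. That choice has a consequence the package
  does not hide: near-deterministic male transitions make successive male
  songs mutually similar, while flexible female transitions randomize female
  phrase order, so the simulated Levenshtein sex contrast comes out
  null-to-reversed rather than male > female as in real birds — the
  acceptance suite measures and reports exactly this. Reproducing the real
  direction appears to require males that switch among several distinct
  song types between renditions, i.e. structure *above* first order, which
  the generator excludes by design. The Levenshtein implementation itself is
  verified independently (exhaustive recursion on all 3-symbol pairs up to
  length 4; 2000 random longer pairs against a second implementation).
* **No acoustics.** Frequency-domain measures, trill-rate analyses and
  waveform synthesis are out of scope; the pipeline begins at annotations.
* **Small-network exclusion is a threshold, not a model.** Birds at 4–5
  types sit just above the cutoff and their density saturates near 1; in
  the synthetic female regime density is effectively at ceiling, so its
  sex contrast is driven primarily by the male side.
* **Problem sizes in the tests** (exhaustive edit-distance enumeration to
  length 4; exhaustive graphs to 5 nodes and 1000 random ones to 8; 2000
  null ANOVA replicates; 20 directional cohort seeds) were chosen to make
  the whole suite run in a few minutes on one core while keeping each check
  statistically meaningful; all are trivially enlargeable.

## Reading real data

`read_textgrid()` parses long- and short-format PRAAT TextGrids in UTF-8 or
UTF-16, returning the non-empty intervals of a named tier (empty labels are
silence); `ingest_textgrids()` chains reading, segmentation and truncation
into a `bird_record`. The flat corpus CSV dialect
(`bird_id,sex,treatment,song_index,onset_s,offset_s,syllable_type`) is the
interchange format between stages, round-trips losslessly, and is what the
`analysis/` drivers consume and produce.
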