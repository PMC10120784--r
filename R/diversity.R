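.check_songs <- function(songs) {
  if (!is.list(songs) || length(songs) == 0L)
    stop("need at least one song", call. = FALSE)
  ok <- vapply(songs, function(s) is.list(s) && length(s$tokens) >= 1L, logical(1))
  if (!all(ok)) stop("every song needs at least one syllable token", call. = FALSE)
  invisible(songs)
}

#' Syllable type repertoire size
#'
#' Number of distinct syllable types over all of a bird's sampled songs.
#'
#' @param songs List of song strings as returned by [song_strings()].
#' @return Integer count.
#' @export
syllable_type_repertoire <- function(songs) {
  .check_songs(songs)
  length(unique(unlist(lapply(songs, `[[`, "tokens"), use.names = FALSE)))
}

#' Song type repertoire size
#'
#' Number of distinct song types. By default (`mode = "type_set"`) songs are
#' typed by their unordered set of syllable types, the convention under which
#' long, individually unique renditions of the same underlying song still
#' count as one type. `mode = "sequence"` instead uses exact ordered
#' label-sequence identity — the strictest reading, but for songs of many
#' dozens of syllables essentially every rendition is unique, so the count
#' saturates at the number of sampled songs.
#'
#' @inheritParams syllable_type_repertoire
#' @param mode `"type_set"` (default) or `"sequence"`.
#' @return Integer count in `[1, length(songs)]`.
#' @export
song_type_repertoire <- function(songs, mode = c("type_set", "sequence")) {
  .check_songs(songs)
  mode <- match.arg(mode)
  keys <- vapply(songs, function(s) {
    toks <- if (mode == "sequence") s$tokens else sort(unique(s$tokens))
    paste(toks, collapse = "\x1f")
  }, character(1))
  length(unique(keys))
}

#' Per-song diversity means
#'
#' Computes, within each song and then averaged over songs with equal weight:
#' number of syllables, number of syllable types, syllables per second,
#' syllable types per second (rates use the song's own duration, first onset
#' to last offset), and the syllable versatility index
#' (SVI = distinct syllable types / syllable tokens, in (0, 1]).
#'
#' @inheritParams syllable_type_repertoire
#' @return Named list with `syllables_per_song`, `syllable_types_per_song`,
#'   `syllables_per_sec`, `syllable_types_per_sec`, `svi`.
#' @export
per_song_means <- function(songs) {
  .check_songs(songs)
  durs <- vapply(songs, `[[`, numeric(1), "duration")
  bad <- which(!is.finite(durs) | durs <= 0)
  if (length(bad))
    stop(sprintf("song %d has non-positive duration", bad[1L]), call. = FALSE)
  n_syl <- vapply(songs, function(s) length(s$tokens), numeric(1))
  n_typ <- vapply(songs, function(s) length(unique(s$tokens)), numeric(1))
  list(syllables_per_song = mean(n_syl),
       syllable_types_per_song = mean(n_typ),
       syllables_per_sec = mean(n_syl / durs),
       syllable_types_per_sec = mean(n_typ / durs),
       svi = mean(n_typ / n_syl))
}

#' Eight diversity metrics for one bird
#'
#' The classical song-diversity panel: syllable type repertoire, song type
#' repertoire, syllables/song, syllable types/song, syllables/sec, syllable
#' types/sec, SVI, and the mean Levenshtein distance between successive songs.
#'
#' @param bird A [bird_record()].
#' @param song_type_mode Passed to [song_type_repertoire()].
#' @return One-row `data.frame` with `bird_id`, `sex`, `treatment`, the eight
#'   metrics, and `n_songs`.
#' @export
diversity_metrics <- function(bird, song_type_mode = "type_set") {
  stopifnot(inherits(bird, "bird_record"))
  songs <- song_strings(bird)
  pm <- per_song_means(songs)
  lev <- if (length(songs) >= 2L) mean_successive_distance(songs) else NA_real_
  data.frame(bird_id = bird$bird_id, sex = bird$sex, treatment = bird$treatment,
             syllable_type_repertoire = syllable_type_repertoire(songs),
             song_type_repertoire = song_type_repertoire(songs, song_type_mode),
             syllables_per_song = pm$syllables_per_song,
             syllable_types_per_song = pm$syllable_types_per_song,
             syllables_per_sec = pm$syllables_per_sec,
             syllable_types_per_sec = pm$syllable_types_per_sec,
             svi = pm$svi,
             levenshtein_mean = lev,
             n_songs = length(songs),
             stringsAsFactors = FALSE)
}

#' Per-bird metric table for a cohort
#'
#' One row per bird: the eight diversity metrics plus, when
#' `networks = TRUE`, the two transition-network metrics (`network_path`,
#' `network_density`), which are `NA` for birds whose network has
#' `small_threshold` or fewer syllable types.
#'
#' @param birds List of [bird_record()]s.
#' @param networks Append network metrics? Default `TRUE`.
#' @param song_type_mode Passed to [song_type_repertoire()].
#' @param respect_song_breaks Passed to [build_network()].
#' @param small_threshold Networks with this many or fewer nodes are excluded
#'   (default 3).
#' @return A `data.frame`, one row per bird.
#' @export
metric_table <- function(birds, networks = TRUE, song_type_mode = "type_set",
                         respect_song_breaks = FALSE, small_threshold = 3L) {
  tab <- do.call(rbind, lapply(birds, diversity_metrics,
                               song_type_mode = song_type_mode))
  if (networks) {
    nm <- do.call(rbind, lapply(birds, function(b) {
      net <- build_network(song_strings(b), respect_song_breaks = respect_song_breaks)
      network_metrics(net, small_threshold = small_threshold)
    }))
    tab$network_path <- nm$path_length
    tab$network_density <- nm$density
    tab$network_n_nodes <- nm$n_nodes
    tab$network_excluded <- nm$excluded
  }
  rownames(tab) <- NULL
  tab
}
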