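#' Run the full diversity-and-syntax analysis
#'
#' From bird records (or a corpus table) to the per-bird metric table, the
#' cell mean/SEM summary, and the three-effects-per-metric ANOVA table —
#' the complete analysis chain.
#'
#' @param birds A list of [bird_record()]s, or a corpus `data.frame` in the
#'   package dialect (converted via [corpus_to_birds()]).
#' @param n_songs Songs retained per bird (default 30).
#' @param song_type_mode Passed to [song_type_repertoire()].
#' @param respect_song_breaks Passed to [build_network()].
#' @param small_threshold Network-exclusion threshold (default 3 nodes).
#' @return A list with `metrics` (per-bird table), `summary` (cell
#'   mean/SEM), `anova` (long ANOVA table), and `config`.
#' @export
run_pipeline <- function(birds, n_songs = 30L, song_type_mode = "type_set",
                         respect_song_breaks = FALSE, small_threshold = 3L) {
  if (is.data.frame(birds)) birds <- corpus_to_birds(birds)
  birds <- lapply(birds, first_n_songs, n = n_songs)
  metrics <- metric_table(birds, networks = TRUE,
                          song_type_mode = song_type_mode,
                          respect_song_breaks = respect_song_breaks,
                          small_threshold = small_threshold)
  list(metrics = metrics,
       summary = summarize_cells(metrics),
       anova = anova_table(metrics),
       config = list(n_songs = n_songs, song_type_mode = song_type_mode,
                     respect_song_breaks = respect_song_breaks,
                     small_threshold = small_threshold, alpha = 0.05))
}

#' Write pipeline outputs to a directory
#'
#' Emits `metrics.csv` (per-bird), `cell_summary.csv` (mean/SEM),
#' `anova.csv` (metric/effect/F/df/p) and `run_log.json` (config, counts,
#' exclusions, package version).
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(result$summary, file.path(dir, "cell_summary.csv"), row.names = FALSE)
  write.csv(result$anova, file.path(dir, "anova.csv"), row.names = FALSE)
  log <- list(package = "songsyntax",
              version = as.character(utils::packageVersion("songsyntax")),
              config = result$config,
              n_birds = nrow(result$metrics),
              n_excluded_networks = sum(result$metrics$network_excluded %||% FALSE))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingest TextGrid annotations for one bird
#'
#' Reads one or more TextGrid files, concatenates their labelled intervals,
#' segments them into songs by the silence/duration rule, and keeps the
#' first `n_songs`.
#'
#' @param paths TextGrid file paths (chronological order).
#' @param bird_id,sex,treatment Identity fields.
#' @param tier_name Interval tier holding syllable labels.
#' @param min_duration,min_silence Segmentation thresholds in seconds.
#' @param n_songs Songs retained.
#' @return A [bird_record()].
#' @export
ingest_textgrids <- function(paths, bird_id, sex, treatment,
                             tier_name = "syllables", min_duration = 1.0,
                             min_silence = 0.4, n_songs = 30L) {
  ivs <- do.call(rbind, lapply(paths, read_textgrid, tier_name = tier_name))
  songs <- segment_songs(ivs, min_duration = min_duration,
                         min_silence = min_silence)
  first_n_songs(bird_record(bird_id, sex, treatment, songs), n = n_songs)
}
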