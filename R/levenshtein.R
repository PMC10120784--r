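#' Levenshtein distance between two syllable sequences
#'
#' Minimum number of single-token insertions, deletions and substitutions
#' converting one syllable-type sequence into the other, at unit cost.
#' Distances are computed over whole tokens, never over the characters of the
#' label text, so multi-character labels behave like atomic symbols.
#'
#' @param a,b Character (or atomic) vectors of syllable-type labels; empty
#'   sequences are allowed.
#' @param normalize If `TRUE`, divide by `max(length(a), length(b))`
#'   (0 for two empty sequences). The default, and the value used throughout
#'   the pipeline, is `FALSE`: raw edit counts.
#' @return A single number: the edit count (or normalized ratio).
#' @export
levenshtein <- function(a, b, normalize = FALSE) {
  a <- as.character(a); b <- as.character(b)
  lv <- c(a, b)
  codes <- match(lv, unique(lv))
  d <- lev_dist_int(codes[seq_along(a)],
                    if (length(b)) codes[length(a) + seq_along(b)] else integer(0))
  if (normalize) {
    m <- max(length(a), length(b))
    if (m == 0L) return(0)
    return(d / m)
  }
  d
}

#' Mean Levenshtein distance between successive songs
#'
#' Variation in syllable-type sequences between successive songs: the mean of
#' the `n - 1` distances between consecutive songs in recording order.
#'
#' @param songs List of song strings as returned by [song_strings()]; at
#'   least two songs are required.
#' @param normalize Passed to [levenshtein()].
#' @return Mean edit count.
#' @export
mean_successive_distance <- function(songs, normalize = FALSE) {
  if (!is.list(songs) || length(songs) < 2L)
    stop("insufficient songs for Levenshtein aggregation (need >= 2)", call. = FALSE)
  d <- vapply(seq_len(length(songs) - 1L), function(i) {
    levenshtein(songs[[i]]$tokens, songs[[i + 1L]]$tokens, normalize = normalize)
  }, numeric(1))
  mean(d)
}
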