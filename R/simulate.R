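#' Define a sex-typed song-generation profile
#'
#' The simulator emits songs from a per-bird first-order Markov chain over
#' syllable types. `transition_determinism` interpolates each type's
#' outgoing (non-self) transition distribution between uniform (0) and
#' one-hot on a preferred successor (1); self-transition mass implements
#' trilling, with mean run length `trill_length_mean` (geometric runs).
#' Timing parameters place syllables on a timeline such that song
#' segmentation at the standard 1 s / 0.4 s rule recovers exactly
#' `songs_per_bird` songs.
#'
#' @param repertoire_size Mean number of syllable types per bird; each bird
#'   draws its own repertoire size from a normal with this mean and
#'   `repertoire_sd`, rounded and floored at 2, reflecting the marked
#'   individual variability of steroid-induced song.
#' @param repertoire_sd Between-bird SD of repertoire size; default
#'   `max(0.75, 0.15 * repertoire_size)`.
#' @param trill_length_mean Expected run length of a repeated syllable type
#'   (>= 1; 1 means no trilling).
#' @param transition_determinism In `[0, 1]`.
#' @param songs_per_bird Songs to generate (default 30).
#' @param song_syllable_count_mean Mean syllables per song (Poisson; default
#'   69, the scale of steroid-induced canary song).
#' @param syllable_duration_s Mean syllable duration in seconds.
#' @param intra_gap_s Within-song silence between syllables (must be
#'   < 0.4 s).
#' @param inter_song_gap_s Minimum silence between songs (>= 0.4 s).
#' @return An object of class `sex_profile`.
#' @export
sex_profile <- function(repertoire_size,
                        repertoire_sd = max(0.75, 0.15 * repertoire_size),
                        trill_length_mean = 3,
                        transition_determinism = 0.5, songs_per_bird = 30L,
                        song_syllable_count_mean = 69,
                        syllable_duration_s = 0.10, intra_gap_s = 0.05,
                        inter_song_gap_s = 0.5) {
  if (repertoire_size < 1) stop("repertoire_size must be >= 1", call. = FALSE)
  if (trill_length_mean < 1)
    stop("infeasible profile: trill_length_mean < 1 implies self-transition mass outside [0, 1)",
         call. = FALSE)
  if (transition_determinism < 0 || transition_determinism > 1)
    stop("transition_determinism must lie in [0, 1]", call. = FALSE)
  if (inter_song_gap_s < 0.4)
    stop("inter_song_gap_s must be >= 0.4 s so song segmentation is exact", call. = FALSE)
  if (intra_gap_s >= 0.4)
    stop("intra_gap_s must be < 0.4 s or songs would be split", call. = FALSE)
  if (repertoire_sd < 0) stop("repertoire_sd must be >= 0", call. = FALSE)
  structure(list(repertoire_size = as.integer(repertoire_size),
                 repertoire_sd = repertoire_sd,
                 trill_length_mean = trill_length_mean,
                 transition_determinism = transition_determinism,
                 songs_per_bird = as.integer(songs_per_bird),
                 song_syllable_count_mean = song_syllable_count_mean,
                 syllable_duration_s = syllable_duration_s,
                 intra_gap_s = intra_gap_s,
                 inter_song_gap_s = inter_song_gap_s),
            class = "sex_profile")
}

#' Default male- and female-typed profiles
#'
#' Male-typed song: larger syllable repertoire (12 types), highly
#' deterministic transitions (0.9), short trills (mean run 3). Female-typed
#' song: small repertoire (5), variable transitions (0.3), long trills (mean
#' run 6). Song length and timing are matched across profiles, so sheer
#' output (syllables per song, syllables per second) carries no sex signal —
#' only diversity and syntax do.
#'
#' @name default_profiles
#' @return A `sex_profile`.
#' @export
male_profile <- function() {
  sex_profile(repertoire_size = 12, trill_length_mean = 3,
              transition_determinism = 0.9)
}

#' @rdname default_profiles
#' @export
female_profile <- function() {
  sex_profile(repertoire_size = 5, trill_length_mean = 6,
              transition_determinism = 0.3)
}

#' Transition matrix for a profile
#'
#' Row `i` puts `1 - 1/trill_length_mean` on the self-transition and spreads
#' the rest over the other types as a determinism-weighted mixture of a
#' uniform distribution and a one-hot distribution on a randomly chosen
#' preferred successor. Uses the current RNG state.
#'
#' @param profile A [sex_profile()].
#' @return A stochastic `k x k` matrix with syllable labels as dimnames.
#' @export
transition_matrix <- function(profile) {
  k <- profile$repertoire_size
  labels <- sprintf("s%02d", seq_len(k))
  if (k == 1L) {
    P <- matrix(1, 1, 1, dimnames = list(labels, labels))
    return(P)
  }
  p_self <- 1 - 1 / profile$trill_length_mean
  d <- profile$transition_determinism
  P <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    preferred <- if (length(others) == 1L) others else sample(others, 1L)
    w <- (1 - d) / (k - 1) + d * (others == preferred)
    P[i, others] <- (1 - p_self) * w / sum(w)
    P[i, i] <- p_self
  }
  P
}

.row_entropy <- function(P) {
  mean(apply(P, 1L, function(p) { p <- p[p > 0]; -sum(p * log(p)) }))
}

.markov_tokens <- function(P, n) {
  k <- nrow(P)
  if (k == 1L) return(rep(rownames(P), n))
  cum <- t(apply(P, 1L, cumsum))
  states <- integer(n)
  states[1L] <- sample.int(k, 1L)
  r <- runif(n)
  for (i in seq_len(n - 1L)) {
    states[i + 1L] <- sum(r[i] > cum[states[i], ]) + 1L
  }
  rownames(P)[states]
}

#' Generate one synthetic bird
#'
#' Draws a per-bird transition matrix from the profile and emits
#' `songs_per_bird` songs of timed syllable intervals, with inter-song
#' silences of at least the profile's `inter_song_gap_s` so that
#' [segment_songs()] recovers the songs exactly. Song lengths are Poisson
#' around `song_syllable_count_mean`, floored so every song exceeds the 1 s
#' minimum. Uses the current RNG state; wrap in `withr::with_seed()` (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param profile A [sex_profile()].
#' @param bird_id,sex,treatment Identity fields for the [bird_record()].
#' @return A `bird_record` with attributes `true_repertoire` and
#'   `true_entropy` (mean outgoing-transition entropy, nats).
#' @export
generate_bird <- function(profile, bird_id = "bird01", sex = "male",
                          treatment = "T") {
  stopifnot(inherits(profile, "sex_profile"))
  k <- max(1L, as.integer(round(stats::rnorm(1, profile$repertoire_size,
                                             profile$repertoire_sd))))
  prof_k <- profile
  prof_k$repertoire_size <- k
  P <- transition_matrix(prof_k)
  dur <- profile$syllable_duration_s
  gap <- profile$intra_gap_s
  min_len <- max(2L, ceiling(1.1 / (0.8 * dur + gap)))
  lens <- pmax(rpois(profile$songs_per_bird, profile$song_syllable_count_mean),
               min_len)
  cursor <- 0.5
  songs <- vector("list", profile$songs_per_bird)
  for (s in seq_len(profile$songs_per_bird)) {
    n <- lens[s]
    tokens <- .markov_tokens(P, n)
    durs <- dur * runif(n, 0.8, 1.2)
    onsets <- cursor + c(0, cumsum(durs[-n] + gap))
    offsets <- onsets + durs
    songs[[s]] <- syllable_intervals(onsets, offsets, tokens)
    cursor <- offsets[n] + profile$inter_song_gap_s + runif(1, 0, 0.3)
  }
  b <- bird_record(bird_id, sex, treatment, songs)
  attr(b, "true_repertoire") <- k
  attr(b, "true_entropy") <- .row_entropy(P)
  b
}

#' Define a synthetic cohort
#'
#' @param n_per_cell Birds per sex x treatment cell (default 7, giving 28
#'   birds and an error df of 24 in the 2 x 2 ANOVA).
#' @param male_profile,female_profile [sex_profile()]s.
#' @param treatment_effect Multiplier applied to the repertoire size of
#'   `T+E2` birds; the default 1.0 encodes a null treatment effect, matching
#'   the biology the simulator emulates. Other values enable power
#'   experiments.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 7L, male_profile = songsyntax::male_profile(),
                        female_profile = songsyntax::female_profile(),
                        treatment_effect = 1.0, seed = 1L) {
  if (n_per_cell < 2) stop("n_per_cell must be >= 2", call. = FALSE)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 male_profile = male_profile, female_profile = female_profile,
                 treatment_effect = treatment_effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic 2 x 2 cohort
#'
#' Two sexes by two steroid treatments (`T`, `T+E2`), `n_per_cell` birds
#' each, 30 songs per bird by default. All randomness flows through the
#' spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `birds` (list of `bird_record`s), `corpus` (the long
#'   interchange table) and `truth` (per-bird generating parameters:
#'   `bird_id,sex,treatment,true_repertoire,true_entropy`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    birds <- list()
    for (sex in c("male", "female")) {
      base_prof <- if (sex == "male") spec$male_profile else spec$female_profile
      for (trt in c("T", "T+E2")) {
        prof <- base_prof
        if (trt == "T+E2" && spec$treatment_effect != 1.0) {
          prof$repertoire_size <- max(1L, as.integer(round(
            prof$repertoire_size * spec$treatment_effect)))
        }
        for (i in seq_len(spec$n_per_cell)) {
          id <- sprintf("%s_%s_%02d", substr(sex, 1, 1),
                        gsub("+", "", trt, fixed = TRUE), i)
          birds[[id]] <- generate_bird(prof, bird_id = id, sex = sex,
                                       treatment = trt)
        }
      }
    }
    truth <- do.call(rbind, lapply(birds, function(b) {
      data.frame(bird_id = b$bird_id, sex = b$sex, treatment = b$treatment,
                 true_repertoire = attr(b, "true_repertoire"),
                 true_entropy = attr(b, "true_entropy"),
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
    list(birds = unname(birds), corpus = birds_to_corpus(birds), truth = truth)
  })
}
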