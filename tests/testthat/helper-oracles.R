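# Independent oracles used across tests. These deliberately share no code
# with the package implementations they check.

# Exhaustive recursive Levenshtein with memoisation; fine for short inputs.
lev_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (a[i] == b[j]) 0L else 1L
    v <- min(rec(i - 1L, j - 1L) + cost,
             rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# Floyd-Warshall mean shortest-path length over mutually reachable pairs of
# an undirected simple graph given as a 0/1 adjacency matrix.
fw_mean_path <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(NA_real_)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  up <- d[upper.tri(d)]
  up <- up[is.finite(up)]
  if (length(up) == 0L) NA_real_ else mean(up)
}

# Realize an arbitrary undirected simple graph as a syllable network by
# feeding one two-token song per edge (plus singleton songs for isolated
# vertices) with song breaks respected, so the undirected view is exactly
# the requested graph.
net_from_adjacency <- function(adj, labels = sprintf("n%02d", seq_len(nrow(adj)))) {
  songs <- list()
  n <- nrow(adj)
  for (i in seq_len(n)) {
    has_edge <- n > 1L && any(adj[i, -i] == 1)
    if (!has_edge) songs[[length(songs) + 1L]] <- list(tokens = labels[i], duration = 1)
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (adj[i, j] == 1) {
        songs[[length(songs) + 1L]] <- list(tokens = c(labels[i], labels[j]),
                                            duration = 1)
      }
    }
  }
  build_network(songs, respect_song_breaks = TRUE)
}

# Songs from compact string notation: one character per syllable token.
make_songs <- function(strings, duration = NULL) {
  lapply(strings, function(s) {
    toks <- strsplit(s, "")[[1]]
    list(tokens = toks,
         duration = if (is.null(duration)) 0.1 * length(toks) else duration)
  })
}

# Random token corpus over a small alphabet.
random_songs <- function(n_songs, min_len = 1L, max_len = 12L,
                         alphabet = c("A", "B", "C", "D", "E")) {
  lapply(seq_len(n_songs), function(i) {
    len <- sample(min_len:max_len, 1L)
    list(tokens = sample(alphabet, len, replace = TRUE),
         duration = 0.1 * len)
  })
}

# Minimal timed bird for IO round-trips: songs laid on a timeline with
# inter-song gaps of `gap` seconds.
timed_bird <- function(strings, bird_id = "b1", sex = "male", treatment = "T",
                       syl_dur = 0.2, intra = 0.1, gap = 0.6) {
  cursor <- 0.25
  songs <- lapply(strings, function(s) {
    toks <- strsplit(s, "")[[1]]
    onsets <- cursor + (seq_along(toks) - 1L) * (syl_dur + intra)
    iv <- syllable_intervals(onsets, onsets + syl_dur, toks)
    cursor <<- max(iv$offset) + gap
    iv
  })
  bird_record(bird_id, sex, treatment, songs)
}
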