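#' Construct a table of syllable intervals
#'
#' The elementary annotation unit is one syllable token: an onset and offset in
#' seconds plus a syllable-type label. Intervals are sorted by onset and
#' validated (positive extent, non-empty label after whitespace stripping,
#' no overlaps).
#'
#' @param onset,offset Numeric vectors of times in seconds.
#' @param label Character vector of syllable-type labels.
#' @return A `data.frame` with columns `onset`, `offset`, `label`, sorted by
#'   onset.
#' @export
syllable_intervals <- function(onset, offset, label) {
  stopifnot(length(onset) == length(offset), length(onset) == length(label))
  label <- trimws(as.character(label))
  if (length(onset) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (any(!is.finite(onset)) || any(!is.finite(offset)))
    stop("non-finite interval times", call. = FALSE)
  if (any(offset <= onset))
    stop("every syllable interval must satisfy offset > onset", call. = FALSE)
  if (any(!nzchar(label)))
    stop("empty syllable labels are not allowed (empty TextGrid intervals are silence and must be dropped upstream)",
         call. = FALSE)
  ord <- order(onset)
  out <- data.frame(onset = onset[ord], offset = offset[ord],
                    label = label[ord], stringsAsFactors = FALSE)
  if (nrow(out) > 1L && any(out$onset[-1L] < out$offset[-nrow(out)] - 1e-9))
    stop("syllable intervals overlap", call. = FALSE)
  rownames(out) <- NULL
  out
}

.detect_textgrid_encoding <- function(path) {
  bom <- readBin(path, "raw", n = 2L)
  if (length(bom) >= 2L) {
    if (bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)) return("UTF-16BE")
    if (bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) return("UTF-16LE")
  }
  "UTF-8"
}

.read_textgrid_lines <- function(path) {
  enc <- .detect_textgrid_encoding(path)
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # strip a UTF-8 BOM if present
  if (length(lines) && grepl("^﻿", lines[1])) lines[1] <- sub("^﻿", "", lines[1])
  lines
}

# Praat doubles embedded quotes inside quoted strings
.unquote_praat <- function(x) gsub('""', '"', x, fixed = TRUE)

.parse_textgrid_long <- function(lines, path) {
  txt <- paste(lines, collapse = "\n")
  # split into per-tier chunks at item [k]:
  starts <- gregexpr("item \\[[0-9]+\\]:", txt)[[1]]
  if (starts[1] == -1L)
    stop(sprintf("malformed long-format TextGrid '%s': no 'item [k]:' blocks found", path),
         call. = FALSE)
  ends <- c(starts[-1L] - 1L, nchar(txt))
  chunks <- substring(txt, starts, ends)
  tier_class <- vapply(chunks, function(ch) {
    m <- regmatches(ch, regexec('class\\s*=\\s*"([^"]*)"', ch))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  tier_name <- vapply(chunks, function(ch) {
    m <- regmatches(ch, regexec('name\\s*=\\s*"((?:[^"]|"")*)"', ch, perl = TRUE))[[1]]
    if (length(m) == 2L) .unquote_praat(m[2]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  list(classes = tier_class, names = tier_name, chunks = chunks)
}

.intervals_from_long_chunk <- function(chunk, path) {
  pat <- paste0('intervals\\s\\[[0-9]+\\]:?\\s*',
                'xmin\\s*=\\s*([0-9.eE+-]+)\\s*',
                'xmax\\s*=\\s*([0-9.eE+-]+)\\s*',
                'text\\s*=\\s*"((?:[^"]|"")*)"')
  m <- gregexpr(pat, chunk, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  hits <- regmatches(chunk, gregexpr(pat, chunk, perl = TRUE))[[1]]
  parts <- regmatches(hits, regexec(pat, hits, perl = TRUE))
  onset <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  offset <- vapply(parts, function(p) as.numeric(p[3]), numeric(1))
  label <- vapply(parts, function(p) .unquote_praat(p[4]), character(1))
  if (any(is.na(onset)) || any(is.na(offset)))
    stop(sprintf("malformed interval times in long-format TextGrid '%s'", path), call. = FALSE)
  data.frame(onset = onset, offset = offset, label = label, stringsAsFactors = FALSE)
}

.parse_textgrid_short <- function(lines, path) {
  vals <- trimws(lines)
  vals <- vals[nzchar(vals)]
  # drop the two header lines and file xmin/xmax/<exists>/ntier
  if (length(vals) < 6L)
    stop(sprintf("malformed short-format TextGrid '%s': fewer than 6 content lines", path),
         call. = FALSE)
  i <- 3L  # after File type / Object class
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vals[k]))
    if (is.na(v))
      stop(sprintf("malformed short-format TextGrid '%s': expected a number at content line %d, got '%s'",
                   path, k, vals[k]), call. = FALSE)
    v
  }
  str <- function(k) {
    v <- vals[k]
    if (!grepl('^".*"$', v))
      stop(sprintf("malformed short-format TextGrid '%s': expected a quoted string at content line %d, got '%s'",
                   path, k, v), call. = FALSE)
    .unquote_praat(sub('^"', "", sub('"$', "", v)))
  }
  i <- i + 2L              # file xmin, xmax consumed
  if (vals[i] != "<exists>")
    stop(sprintf("malformed short-format TextGrid '%s': expected '<exists>' at content line %d", path, i),
         call. = FALSE)
  ntier <- as.integer(num(i + 1L))
  i <- i + 2L
  classes <- character(ntier); names_ <- character(ntier)
  tiers <- vector("list", ntier)
  for (t in seq_len(ntier)) {
    classes[t] <- str(i); names_[t] <- str(i + 1L)
    i <- i + 4L            # class, name, tier xmin, tier xmax
    n <- as.integer(num(i)); i <- i + 1L
    if (classes[t] == "IntervalTier") {
      onset <- offset <- numeric(n); label <- character(n)
      for (k in seq_len(n)) {
        onset[k] <- num(i); offset[k] <- num(i + 1L); label[k] <- str(i + 2L)
        i <- i + 3L
      }
      tiers[[t]] <- data.frame(onset = onset, offset = offset, label = label,
                               stringsAsFactors = FALSE)
    } else {
      i <- i + 2L * n      # point tier: time + mark pairs, skipped
      tiers[[t]] <- NULL
    }
  }
  list(classes = classes, names = names_, tiers = tiers)
}

#' Read syllable intervals from a PRAAT TextGrid
#'
#' Parses long- or short-format TextGrid files (UTF-8 or UTF-16) and returns
#' the non-empty-labelled intervals of one interval tier, sorted by onset.
#' Empty labels mark silence and are dropped. If `tier_name` is absent but the
#' file contains exactly one interval tier, that tier is used with a message.
#'
#' @param path Path to a TextGrid file.
#' @param tier_name Name of the interval tier holding syllable labels.
#' @return A syllable-interval `data.frame` (see [syllable_intervals()]).
#' @export
read_textgrid <- function(path, tier_name = "syllables") {
  if (!file.exists(path)) stop(sprintf("TextGrid not found: '%s'", path), call. = FALSE)
  lines <- .read_textgrid_lines(path)
  if (!any(grepl("ooTextFile", lines, fixed = TRUE)) ||
      !any(grepl("TextGrid", lines, fixed = TRUE)))
    stop(sprintf("'%s' does not look like a PRAAT TextGrid (missing header)", path),
         call. = FALSE)
  long <- any(grepl("item \\[", lines))
  if (long) {
    parsed <- .parse_textgrid_long(lines, path)
    is_int <- parsed$classes == "IntervalTier"
    idx <- which(is_int & parsed$names == tier_name)
    if (length(idx) == 0L) {
      if (sum(is_int) == 1L) {
        idx <- which(is_int)
        message(sprintf("tier '%s' not found; using the only interval tier '%s'",
                        tier_name, parsed$names[idx]))
      } else {
        stop(sprintf("no interval tier named '%s' in '%s'; available tiers: %s",
                     tier_name, path,
                     paste(sprintf("'%s' (%s)", parsed$names, parsed$classes), collapse = ", ")),
             call. = FALSE)
      }
    }
    iv <- .intervals_from_long_chunk(parsed$chunks[[idx[1]]], path)
  } else {
    parsed <- .parse_textgrid_short(lines, path)
    is_int <- parsed$classes == "IntervalTier"
    idx <- which(is_int & parsed$names == tier_name)
    if (length(idx) == 0L) {
      if (sum(is_int) == 1L) {
        idx <- which(is_int)
        message(sprintf("tier '%s' not found; using the only interval tier '%s'",
                        tier_name, parsed$names[idx]))
      } else {
        stop(sprintf("no interval tier named '%s' in '%s'; available tiers: %s",
                     tier_name, path,
                     paste(sprintf("'%s' (%s)", parsed$names, parsed$classes), collapse = ", ")),
             call. = FALSE)
      }
    }
    iv <- parsed$tiers[[idx[1]]]
  }
  iv$label <- trimws(iv$label)
  iv <- iv[nzchar(iv$label), , drop = FALSE]
  syllable_intervals(iv$onset, iv$offset, iv$label)
}

#' Write syllable intervals to a long-format TextGrid
#'
#' Silence between annotated syllables is filled with empty-labelled
#' intervals so the tier tiles `[xmin, xmax]` as PRAAT requires.
#'
#' @param intervals Syllable-interval `data.frame`.
#' @param path Output path.
#' @param tier_name Tier name to write.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(intervals, path, tier_name = "syllables") {
  iv <- syllable_intervals(intervals$onset, intervals$offset, intervals$label)
  xmin <- if (nrow(iv)) min(iv$onset) else 0
  xmax <- if (nrow(iv)) max(iv$offset) else 1
  # tile with silence gaps
  bounds <- data.frame(onset = numeric(0), offset = numeric(0), label = character(0))
  cur <- xmin
  for (k in seq_len(nrow(iv))) {
    if (iv$onset[k] > cur + 1e-12)
      bounds <- rbind(bounds, data.frame(onset = cur, offset = iv$onset[k], label = ""))
    bounds <- rbind(bounds, iv[k, , drop = FALSE])
    cur <- iv$offset[k]
  }
  if (cur < xmax - 1e-12)
    bounds <- rbind(bounds, data.frame(onset = cur, offset = xmax, label = ""))
  q <- function(x) gsub('"', '""', x, fixed = TRUE)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           sprintf("xmin = %.10g", xmin), sprintf("xmax = %.10g", xmax),
           "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
           '        class = "IntervalTier"',
           sprintf('        name = "%s"', q(tier_name)),
           sprintf("        xmin = %.10g", xmin), sprintf("        xmax = %.10g", xmax),
           sprintf("        intervals: size = %d", nrow(bounds)))
  for (k in seq_len(nrow(bounds))) {
    out <- c(out,
             sprintf("        intervals [%d]:", k),
             sprintf("            xmin = %.10g", bounds$onset[k]),
             sprintf("            xmax = %.10g", bounds$offset[k]),
             sprintf('            text = "%s"', q(bounds$label[k])))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Segment a syllable stream into songs
#'
#' A song is a maximal run of syllables in which every silence gap
#' (next onset minus current offset) is shorter than `min_silence`, and whose
#' total extent (last offset minus first onset) is at least `min_duration`.
#' A gap exactly equal to `min_silence` splits: the rule is that songs are
#' bounded by at least that much silence. Bouts shorter than `min_duration`
#' are discarded but kept in the `discarded` attribute so no token is lost.
#'
#' @param intervals Sorted, non-overlapping syllable-interval `data.frame`.
#' @param min_duration Minimum song extent in seconds (default 1.0).
#' @param min_silence Minimum separating silence in seconds (default 0.4).
#' @return A list of syllable-interval `data.frame`s, one per song, in
#'   temporal order, with attributes `discarded` (list of sub-threshold bouts)
#'   and `n_discarded`.
#' @export
segment_songs <- function(intervals, min_duration = 1.0, min_silence = 0.4) {
  iv <- syllable_intervals(intervals$onset, intervals$offset, intervals$label)
  if (nrow(iv) == 0L) {
    out <- list()
    attr(out, "discarded") <- list()
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  gaps <- iv$onset[-1L] - iv$offset[-nrow(iv)]
  breakpt <- which(gaps >= min_silence - 1e-12)
  bout_id <- cumsum(c(1L, as.integer(seq_len(nrow(iv) - 1L) %in% breakpt)))
  bouts <- split(iv, bout_id)
  keep <- vapply(bouts, function(b) {
    (b$offset[nrow(b)] - b$onset[1L]) >= min_duration - 1e-12
  }, logical(1))
  songs <- unname(bouts[keep])
  songs <- lapply(songs, function(s) { rownames(s) <- NULL; s })
  attr(songs, "discarded") <- unname(bouts[!keep])
  attr(songs, "n_discarded") <- sum(!keep)
  songs
}

#' Construct a bird record
#'
#' @param bird_id Bird identifier.
#' @param sex `"male"` or `"female"`.
#' @param treatment `"T"`, `"T+E2"` or `"control"`.
#' @param songs List of syllable-interval `data.frame`s in temporal order.
#' @return An object of class `bird_record`.
#' @export
bird_record <- function(bird_id, sex, treatment, songs) {
  sex <- match.arg(sex, c("male", "female"))
  treatment <- match.arg(treatment, c("T", "T+E2", "control"))
  stopifnot(is.list(songs))
  structure(list(bird_id = as.character(bird_id), sex = sex,
                 treatment = treatment, songs = songs),
            class = "bird_record")
}

#' @export
print.bird_record <- function(x, ...) {
  cat(sprintf("<bird_record> %s (%s, %s): %d songs, %d syllables\n",
              x$bird_id, x$sex, x$treatment, length(x$songs),
              sum(vapply(x$songs, nrow, integer(1)))))
  invisible(x)
}

#' Keep the first n songs of a bird
#'
#' The analysis sample is the first `n` (default 30) songs each bird
#' produced. If fewer are available the record is flagged `underfilled`.
#'
#' @param bird A [bird_record()].
#' @param n Number of songs to retain.
#' @return The truncated `bird_record` with attributes `n_retained` and
#'   `underfilled`.
#' @export
first_n_songs <- function(bird, n = 30L) {
  stopifnot(inherits(bird, "bird_record"))
  k <- min(length(bird$songs), n)
  bird$songs <- bird$songs[seq_len(k)]
  attr(bird, "n_retained") <- k
  attr(bird, "underfilled") <- k < n
  bird
}

#' Convert a bird record to per-song token sequences
#'
#' @param bird A [bird_record()].
#' @return A list with one element per song, each a list with `tokens`
#'   (character vector of syllable-type labels in order) and `duration`
#'   (seconds, first onset to last offset).
#' @export
song_strings <- function(bird) {
  stopifnot(inherits(bird, "bird_record"))
  lapply(bird$songs, function(s) {
    list(tokens = s$label, duration = s$offset[nrow(s)] - s$onset[1L])
  })
}

.corpus_cols <- c("bird_id", "sex", "treatment", "song_index",
                  "onset_s", "offset_s", "syllable_type")

#' Flatten bird records into the long corpus table
#'
#' One row per syllable token with the header
#' `bird_id,sex,treatment,song_index,onset_s,offset_s,syllable_type`
#' (1-based song_index). This flat table is the package's interchange format.
#'
#' @param birds List of [bird_record()]s.
#' @return A long `data.frame`.
#' @export
birds_to_corpus <- function(birds) {
  rows <- lapply(birds, function(b) {
    stopifnot(inherits(b, "bird_record"))
    per_song <- lapply(seq_along(b$songs), function(i) {
      s <- b$songs[[i]]
      data.frame(bird_id = b$bird_id, sex = b$sex, treatment = b$treatment,
                 song_index = i, onset_s = s$onset, offset_s = s$offset,
                 syllable_type = s$label, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_song)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild bird records from the long corpus table
#'
#' @param corpus A `data.frame` in the package corpus dialect.
#' @return A list of [bird_record()]s ordered by first appearance.
#' @export
corpus_to_birds <- function(corpus) {
  miss <- setdiff(.corpus_cols, names(corpus))
  if (length(miss))
    stop(sprintf("corpus table is missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  ids <- unique(corpus$bird_id)
  lapply(ids, function(id) {
    cb <- corpus[corpus$bird_id == id, , drop = FALSE]
    songs <- lapply(sort(unique(cb$song_index)), function(i) {
      s <- cb[cb$song_index == i, , drop = FALSE]
      syllable_intervals(s$onset_s, s$offset_s, s$syllable_type)
    })
    bird_record(id, cb$sex[1L], cb$treatment[1L], songs)
  })
}

#' @rdname birds_to_corpus
#' @param path CSV path.
#' @export
write_corpus_csv <- function(birds, path) {
  corpus <- if (is.data.frame(birds)) birds else birds_to_corpus(birds)
  write.csv(corpus, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname corpus_to_birds
#' @param path CSV path.
#' @export
read_corpus_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
           colClasses = c(bird_id = "character", syllable_type = "character"))
}
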