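long_textgrid_lines <- function(intervals, tier = "syllables", extra_tier = FALSE) {
  # intervals: data.frame(onset, offset, label) in the STORAGE order given
  n <- nrow(intervals)
  xmax <- max(intervals$offset)
  body <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
            "xmin = 0", sprintf("xmax = %g", xmax),
            "tiers? <exists>",
            sprintf("size = %d", if (extra_tier) 2L else 1L),
            "item []:", "    item [1]:",
            '        class = "IntervalTier"',
            sprintf('        name = "%s"', tier),
            "        xmin = 0", sprintf("        xmax = %g", xmax),
            sprintf("        intervals: size = %d", n))
  for (k in seq_len(n)) {
    body <- c(body,
              sprintf("        intervals [%d]:", k),
              sprintf("            xmin = %g", intervals$onset[k]),
              sprintf("            xmax = %g", intervals$offset[k]),
              sprintf('            text = "%s"', intervals$label[k]))
  }
  if (extra_tier) {
    body <- c(body, "    item [2]:",
              '        class = "IntervalTier"', '        name = "notes"',
              "        xmin = 0", sprintf("        xmax = %g", xmax),
              "        intervals: size = 1",
              "        intervals [1]:", "            xmin = 0",
              sprintf("            xmax = %g", xmax), '            text = ""')
  }
  body
}

short_textgrid_lines <- function(intervals, tier = "syllables") {
  xmax <- max(intervals$offset)
  body <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
            "0", sprintf("%g", xmax), "<exists>", "1",
            '"IntervalTier"', sprintf('"%s"', tier), "0", sprintf("%g", xmax),
            sprintf("%d", nrow(intervals)))
  for (k in seq_len(nrow(intervals))) {
    body <- c(body, sprintf("%g", intervals$onset[k]),
              sprintf("%g", intervals$offset[k]),
              sprintf('"%s"', intervals$label[k]))
  }
  body
}

write_utf16le <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xFF, 0xFE)), con)
  raw <- iconv(paste0(paste(lines, collapse = "\r\n"), "\r\n"),
               from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
  writeBin(raw, con)
}

shuffled_fixture <- function() {
  # 6 labeled + 2 silence intervals, stored in shuffled (non-temporal) order
  iv <- data.frame(onset = c(0.9, 0.0, 0.6, 0.15, 1.2, 0.3, 0.45, 1.05),
                   offset = c(1.0, 0.1, 0.7, 0.3, 1.35, 0.45, 0.6, 1.2),
                   label = c("E", "A", "D", "", "F", "B", "C", ""))
  iv
}

test_that("long-format TextGrids parse: silence dropped, intervals sorted by onset", {
  iv <- shuffled_fixture()
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_textgrid_lines(iv), tg)
  out <- read_textgrid(tg, "syllables")
  expect_equal(nrow(out), 6L)
  expect_equal(out$label, c("A", "B", "C", "D", "E", "F"))
  expect_true(all(diff(out$onset) > 0))
  expect_equal(out$onset[1], 0.0)
  expect_equal(out$offset[6], 1.35)
})

test_that("short-format and UTF-16 TextGrids parse to the same intervals", {
  iv <- shuffled_fixture()
  tg_long <- withr::local_tempfile(fileext = ".TextGrid")
  tg_short <- withr::local_tempfile(fileext = ".TextGrid")
  tg_utf16 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_textgrid_lines(iv), tg_long)
  writeLines(short_textgrid_lines(iv), tg_short)
  write_utf16le(long_textgrid_lines(iv), tg_utf16)
  ref <- read_textgrid(tg_long)
  expect_equal(read_textgrid(tg_short), ref)
  expect_equal(read_textgrid(tg_utf16), ref)
})

test_that("an empty tier yields an empty interval table", {
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  iv <- data.frame(onset = 0, offset = 1, label = "")
  writeLines(long_textgrid_lines(iv), tg)
  out <- read_textgrid(tg)
  expect_equal(nrow(out), 0L)
})

test_that("missing tiers name the available ones; a sole interval tier is used with notice", {
  iv <- shuffled_fixture()
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_textgrid_lines(iv, tier = "syll", extra_tier = TRUE), tg)
  expect_error(read_textgrid(tg, "syllables"), "available tiers.*syll.*notes")
  tg2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_textgrid_lines(iv, tier = "voc"), tg2)
  expect_message(out <- read_textgrid(tg2, "syllables"), "only interval tier")
  expect_equal(nrow(out), 6L)
  tg3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("not", "a", "textgrid"), tg3)
  expect_error(read_textgrid(tg3), "header")
})

test_that("written TextGrids round-trip through both the writer and reader", {
  iv <- shuffled_fixture()
  iv <- syllable_intervals(iv$onset[nzchar(iv$label)], iv$offset[nzchar(iv$label)],
                           iv$label[nzchar(iv$label)])
  tg <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(iv, tg)
  back <- read_textgrid(tg)
  expect_equal(back$onset, iv$onset, tolerance = 1e-9)
  expect_equal(back$offset, iv$offset, tolerance = 1e-9)
  expect_equal(back$label, iv$label)
})

test_that("songs are split at gaps of at least the minimum silence, short bouts discarded", {
  # two bouts (durations 1.2 s and 1.4 s) separated by a 0.5 s gap;
  # within-bout gaps 0.1 s
  b1 <- data.frame(onset = c(0.0, 0.5, 1.0), offset = c(0.4, 0.9, 1.2),
                   label = c("A", "B", "A"))
  b2 <- data.frame(onset = c(1.7, 2.4, 2.9), offset = c(2.3, 2.8, 3.1),
                   label = c("C", "A", "B"))
  songs <- segment_songs(rbind(b1, b2))
  expect_length(songs, 2L)
  expect_equal(songs[[1]]$label, c("A", "B", "A"))
  expect_equal(songs[[2]]$label, c("C", "A", "B"))
  expect_equal(attr(songs, "n_discarded"), 0L)

  # a lone 0.8 s bout is below the 1 s minimum
  short <- data.frame(onset = c(0, 0.5), offset = c(0.4, 0.8), label = c("A", "B"))
  out <- segment_songs(short)
  expect_length(out, 0L)
  expect_equal(attr(out, "n_discarded"), 1L)

  # a gap of exactly 0.4 s is a valid separator: the bout splits
  iv <- data.frame(onset = c(0.0, 1.5, 1.9), offset = c(1.1, 1.8, 3.0),
                   label = c("A", "B", "C"))
  expect_length(segment_songs(iv), 2L)
  # just under 0.4 s does not split
  iv2 <- iv; iv2$onset[2] <- 1.49
  expect_length(segment_songs(iv2), 1L)

  expect_length(segment_songs(iv[0, ]), 0L)
})

test_that("every input token lands in exactly one song or the discarded log", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(5:60, 1)
      gaps <- sample(c(0.05, 0.2, 0.45, 0.8), n, replace = TRUE)
      durs <- runif(n, 0.05, 0.6)
      onsets <- cumsum(c(0, head(durs, -1) + head(gaps, -1)))
      iv <- syllable_intervals(onsets, onsets + durs,
                               sample(LETTERS[1:4], n, replace = TRUE))
      segs <- segment_songs(iv)
      kept <- do.call(rbind, c(segs, attr(segs, "discarded")))
      kept <- kept[order(kept$onset), ]
      rownames(kept) <- NULL
      expect_equal(kept, iv)
    }
  })
})

test_that("segmentation is idempotent on already-segmented songs", {
  b <- timed_bird(c("ABAB", "CDCD", "AACC"))
  iv <- do.call(rbind, b$songs)
  once <- segment_songs(iv)
  again <- segment_songs(do.call(rbind, once))
  expect_equal(unname(lapply(again, `[[`, "label")),
               unname(lapply(once, `[[`, "label")))
})

test_that("first_n_songs truncates, flags underfilled corpora, and is identity at n", {
  b45 <- timed_bird(rep("ABCD", 45))
  expect_equal(attr(first_n_songs(b45), "n_retained"), 30L)
  expect_length(first_n_songs(b45)$songs, 30L)
  expect_false(attr(first_n_songs(b45), "underfilled"))

  b12 <- timed_bird(rep("ABCD", 12))
  expect_equal(attr(first_n_songs(b12), "n_retained"), 12L)
  expect_true(attr(first_n_songs(b12), "underfilled"))

  b30 <- timed_bird(rep("ABCD", 30))
  expect_equal(first_n_songs(b30)$songs, b30$songs)
})

test_that("the corpus CSV dialect round-trips labels and times", {
  birds <- list(timed_bird(c("ABAB", "CDCD"), bird_id = "b1"),
                timed_bird(c("AABB", "ABCD", "DDDD"), bird_id = "b2",
                           sex = "female", treatment = "T+E2"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_corpus_csv(birds, csv)
  expect_equal(readLines(csv, n = 1),
               "bird_id,sex,treatment,song_index,onset_s,offset_s,syllable_type")
  back <- corpus_to_birds(read_corpus_csv(csv))
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$bird_id, birds[[i]]$bird_id)
    expect_equal(back[[i]]$sex, birds[[i]]$sex)
    expect_equal(back[[i]]$treatment, birds[[i]]$treatment)
    for (s in seq_along(birds[[i]]$songs)) {
      expect_equal(back[[i]]$songs[[s]]$onset, birds[[i]]$songs[[s]]$onset,
                   tolerance = 1e-6)
      expect_equal(back[[i]]$songs[[s]]$label, birds[[i]]$songs[[s]]$label)
    }
  }
  expect_error(corpus_to_birds(data.frame(bird_id = "x")), "missing columns")
})

test_that("interval validation rejects inverted times, overlaps and empty labels", {
  expect_error(syllable_intervals(1, 0.5, "A"), "offset > onset")
  expect_error(syllable_intervals(c(0, 0.2), c(0.3, 0.5), c("A", "B")), "overlap")
  expect_error(syllable_intervals(0, 1, "  "), "empty")
})
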