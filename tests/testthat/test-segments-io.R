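test_that("TextGrid parsing copies intervals and inserts gap silences", {
  tg <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
          "xmin = 0", "xmax = 0.6", "tiers? <exists>", "size = 1", "item []:",
          "    item [1]:", '        class = "IntervalTier"',
          '        name = "phones"', "        xmin = 0", "        xmax = 0.6",
          "        intervals: size = 3",
          "        intervals [1]:", "            xmin = 0",
          "            xmax = 0.05", '            text = "p"',
          "        intervals [2]:", "            xmin = 0.05",
          "            xmax = 0.20", '            text = "aa1"',
          "        intervals [3]:", "            xmin = 0.40",
          "            xmax = 0.60", '            text = "k"')
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(tg, path)
  s <- read_textgrid(path, c(phone = "phones"))
  ph <- s$segments[s$segments$kind == "phone", ]
  expect_equal(nrow(ph), 3)
  expect_equal(ph$end_s - ph$start_s, c(0.05, 0.15, 0.20))
  # the 0.20-0.40 gap becomes a silence
  sil <- s$segments[s$segments$kind == "silence", ]
  expect_true(any(abs(sil$start_s - 0.20) < 1e-9 & abs(sil$end_s - 0.40) < 1e-9))
})

test_that("TextGrid write/read round trip preserves segments", {
  s <- tiny_ddk_sample(n_trials = 12, k = 4)
  path <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(s, path)
  s2 <- read_textgrid(path, c(phone = "phones", trial = "trials"),
                      participant_id = s$participant_id, task = "AMR")
  ph1 <- s$segments[s$segments$kind == "phone", ]
  ph2 <- s2$segments[s2$segments$kind == "phone", ]
  expect_equal(nrow(ph1), nrow(ph2))
  expect_equal(ph2$start_s, ph1$start_s, tolerance = 1e-9)
  expect_equal(ph2$end_s, ph1$end_s, tolerance = 1e-9)
  expect_identical(ph2$label, ph1$label)
  expect_equal(s2$trial_windows, s$trial_windows, tolerance = 1e-9)
})

test_that("malformed TextGrids raise named parse errors", {
  path <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c("not a textgrid", "at all"), path)
  expect_error(read_textgrid(path, c(phone = "phones")), "ooTextFile")
  expect_error(read_textgrid("no/such/file.TextGrid", c(phone = "phones")),
               "not found")
  # missing mapped tier
  s <- tiny_ddk_sample(n_trials = 12, k = 3)
  write_textgrid(s, path)
  expect_error(read_textgrid(path, c(phone = "segments")), "not present")
})

test_that("segment CSV write/read is the identity on all fields", {
  set.seed(10)
  cfg <- small_synth_config(tasks = c("AMR", "READ"), n = 1L)
  co <- generate_cohort(cfg, seed = 3, detail = "segments")
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(co$samples, path)
  back <- read_segments_csv(path)
  expect_length(back, length(co$samples))
  for (s in co$samples) {
    hit <- which(vapply(back, function(b)
      b$participant_id == s$participant_id && b$task == s$task, logical(1)))
    expect_length(hit, 1)
    b <- back[[hit]]
    expect_identical(b$task, s$task)
    a_seg <- s$segments[order(s$segments$kind, s$segments$start_s), ]
    b_seg <- b$segments[order(b$segments$kind, b$segments$start_s), ]
    rownames(a_seg) <- rownames(b_seg) <- NULL
    expect_equal(b_seg, a_seg, tolerance = 1e-12)
  }
})

test_that("segment CSV errors are row-precise", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("participant_id", "task", "modality", "kind", "label",
                 "start_s", "end_s", "vot_s", "f1_20", "f2_20", "f1_50",
                 "f2_50", "stress"), collapse = ",")
  writeLines(c(hdr,
               'p1,READ,in_person,phone,AA1,0.0,0.5,,,,,,primary',
               'p1,READ,in_person,phone,K,abc,0.9,,,,,,'), path)
  expect_error(read_segments_csv(path), "row")
  writeLines(c("participant_id,task", "p1,READ"), path)
  expect_error(read_segments_csv(path), "missing required column")
})

test_that("stop token selection follows the prevocalic syllable-initial rule", {
  # word-initial p before vowel: selected; p before r ("prism"): not
  seg <- data.frame(
    label = c("P", "AE1", "S", "P", "R", "IH1", "Z", "M"),
    kind = "phone",
    start_s = c(0.0, 0.06, 0.20, 0.26, 0.32, 0.38, 0.50, 0.56),
    end_s = c(0.06, 0.20, 0.26, 0.32, 0.38, 0.50, 0.56, 0.62))
  s <- speech_sample("x", "READ", "in_person", seg)
  tk <- select_stop_tokens(s, "voiceless")
  expect_equal(nrow(tk), 1)
  expect_identical(tk$label, "P")
  expect_equal(tk$vot, 0.06)

  # stop after a non-vowel consonant, not word-initial: excluded
  seg2 <- data.frame(label = c("S", "K", "AA1"), kind = "phone",
                     start_s = c(0, 0.08, 0.14), end_s = c(0.08, 0.14, 0.30))
  s2 <- speech_sample("x", "READ", "in_person", seg2)
  expect_equal(nrow(select_stop_tokens(s2, "voiceless")), 0)
  # ... but selected when it starts a word
  seg2w <- rbind(seg2, data.frame(label = "cat", kind = "word",
                                  start_s = 0.08, end_s = 0.30))
  s2w <- speech_sample("x", "READ", "in_person", seg2w)
  expect_equal(nrow(select_stop_tokens(s2w, "voiceless")), 1)

  # stop preceded by silence: selected
  seg3 <- data.frame(label = c("AA1", "", "T", "IY1"),
                     kind = c("phone", "silence", "phone", "phone"),
                     start_s = c(0, 0.2, 0.5, 0.56),
                     end_s = c(0.2, 0.5, 0.56, 0.7))
  s3 <- speech_sample("x", "READ", "in_person", seg3)
  expect_equal(nrow(select_stop_tokens(s3, "voiceless")), 1)
})

test_that("voiced selection uses vot_s, drops prevoicing, refuses DDK", {
  seg <- data.frame(label = c("B", "AA1", "D", "IY1"), kind = "phone",
                    start_s = c(0, 0.08, 0.3, 0.4), end_s = c(0.08, 0.3, 0.4, 0.6),
                    vot_s = c(0.012, NA, -0.03, NA))
  s <- speech_sample("x", "READ", "in_person", seg)
  tk <- select_stop_tokens(s, "voiced")
  expect_equal(nrow(tk), 1)          # prevoiced token dropped
  expect_equal(tk$vot, 0.012)        # vot_s attribute preferred over duration
  expect_equal(attr(tk, "n_prevoiced"), 1L)
  expect_error(select_stop_tokens(tiny_ddk_sample(), "voiced"), "voiceless")
})

test_that("stressed vowel selection keeps primary stress only, DDK keeps all", {
  # element-like stress pattern: IH0 L EH1 M -> only EH1
  seg <- data.frame(label = c("IH0", "L", "EH1", "M"), kind = "phone",
                    start_s = c(0, 0.1, 0.2, 0.35), end_s = c(0.1, 0.2, 0.35, 0.45))
  s <- speech_sample("x", "READ", "in_person", seg)
  tk <- select_stressed_vowel_tokens(s)
  expect_equal(nrow(tk), 1)
  expect_identical(tk$label, "EH1")
  expect_equal(tk$duration, 0.15)

  # DDK: all vowels count as stressed
  amr <- tiny_ddk_sample(n_trials = 12, k = 15)
  expect_equal(nrow(select_stressed_vowel_tokens(amr)), 180)

  # consonants only -> empty with a warning
  seg3 <- data.frame(label = c("S", "T"), kind = "phone",
                     start_s = c(0, 0.1), end_s = c(0.1, 0.2))
  s3 <- speech_sample("x", "READ", "in_person", seg3)
  expect_warning(tk3 <- select_stressed_vowel_tokens(s3), "no vowel")
  expect_equal(nrow(tk3), 0)
})

test_that("removing a segment never adds tokens (selection monotonicity)", {
  set.seed(21)
  co <- generate_cohort(small_synth_config(tasks = "READ", n = 1L), seed = 5,
                        detail = "segments")
  s <- co$samples[[1]]
  full <- nrow(select_stop_tokens(s, "voiceless"))
  ph_idx <- which(s$segments$kind == "phone")
  for (drop in sample(ph_idx, 10)) {
    s2 <- s
    s2$segments <- s$segments[-drop, ]
    n2 <- nrow(suppressWarnings(select_stop_tokens(s2, "voiceless")))
    expect_lte(n2, full)
  }
})

test_that("phone plus silence time tiles generated samples", {
  co <- generate_cohort(small_synth_config(tasks = c("AMR", "SPONT"), n = 2L),
                        seed = 9, detail = "segments")
  for (s in co$samples) {
    seg <- s$segments[s$segments$kind %in% c("phone", "silence"), ]
    covered <- sum(seg$end_s - seg$start_s)
    expect_equal(covered, s$total_duration_s, tolerance = 1e-6)
  }
})

test_that("speech sample invariants are enforced", {
  bad <- data.frame(label = "AA1", kind = "phone", start_s = 1, end_s = 0.5)
  expect_error(speech_sample("x", "READ", "in_person", bad), "end_s")
  over <- data.frame(label = c("AA1", "IY1"), kind = "phone",
                     start_s = c(0, 0.1), end_s = c(0.3, 0.4))
  expect_error(speech_sample("x", "READ", "in_person", over), "overlap")
  vot_bad <- data.frame(label = "P", kind = "phone", start_s = 0, end_s = 0.05,
                        vot_s = 0.2)
  expect_error(speech_sample("x", "READ", "in_person", vot_bad), "vot")
  expect_warning(
    speech_sample("x", "AMR", "in_person",
                  data.frame(label = "AA1", kind = "phone", start_s = 0, end_s = 1),
                  trial_windows = data.frame(start_s = 0, end_s = 1)),
    "incomplete")
})
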