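# small hand-built samples used across test files

# one READ-style sample: "p AA1 t IY0 | 200 ms silence | k EH1" plus words
tiny_read_sample <- function() {
  seg <- data.frame(
    label = c("P", "AA1", "T", "IY0", "", "K", "EH1"),
    kind = c("phone", "phone", "phone", "phone", "silence", "phone", "phone"),
    start_s = c(0.00, 0.05, 0.20, 0.28, 0.40, 0.60, 0.66),
    end_s = c(0.05, 0.20, 0.28, 0.40, 0.60, 0.66, 0.80),
    stringsAsFactors = FALSE)
  speech_sample("p1", "READ", "in_person", seg, total_duration_s = 0.8)
}

# a DDK sample with explicit trial windows: n_trials x k CV syllables
tiny_ddk_sample <- function(task = "AMR", n_trials = 12, k = 3,
                            stop_label = "P", vot = 0.05, vowel = 0.10,
                            gap = 0.02, trial_gap = 0.5) {
  rows <- list()
  tw <- matrix(0, n_trials, 2)
  t0 <- 0.2
  for (tr in seq_len(n_trials)) {
    start_tr <- t0
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = c(stop_label, "AA1"), kind = "phone",
        start_s = c(t0, t0 + vot), end_s = c(t0 + vot, t0 + vot + vowel),
        stringsAsFactors = FALSE)
      t0 <- t0 + vot + vowel + if (j < k) gap else 0
    }
    tw[tr, ] <- c(start_tr, t0)
    t0 <- t0 + trial_gap
  }
  seg <- do.call(rbind, rows)
  speech_sample("d1", task, "in_person", seg,
                trial_windows = data.frame(start_s = tw[, 1], end_s = tw[, 2]),
                total_duration_s = t0)
}

# vowel token set with explicit formants
formant_tokens <- function(f1_20, f2_20, f1_50 = f1_20, f2_50 = f2_20,
                           labels = NULL) {
  n <- length(f1_20)
  if (is.null(labels)) labels <- rep("AA1", n)
  df <- data.frame(label = labels, kind = "phone",
                   start_s = seq_len(n) * 0.2, end_s = seq_len(n) * 0.2 + 0.1,
                   vot_s = NA_real_, f1_20 = f1_20, f2_20 = f2_20,
                   f1_50 = f1_50, f2_50 = f2_50, stress = "primary",
                   stringsAsFactors = FALSE)
  structure(df, class = c("token_set", "data.frame"))
}

# connected-speech sample built from (phrase lengths, silence durations):
# phrases of `syls` vowels, separated by the given silences
phrase_timeline_sample <- function(speech_durs, sil_durs, task = "READ",
                                   lead = 0, trail = 0) {
  stopifnot(length(sil_durs) == length(speech_durs) - 1)
  rows <- list()
  t0 <- lead
  for (i in seq_along(speech_durs)) {
    # one vowel phone spanning the whole spoken stretch
    rows[[length(rows) + 1L]] <- data.frame(
      label = "AA1", kind = "phone", start_s = t0,
      end_s = t0 + speech_durs[i], stringsAsFactors = FALSE)
    t0 <- t0 + speech_durs[i]
    if (i < length(speech_durs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = "", kind = "silence", start_s = t0, end_s = t0 + sil_durs[i],
        stringsAsFactors = FALSE)
      t0 <- t0 + sil_durs[i]
    }
  }
  seg <- do.call(rbind, rows)
  speech_sample("t1", task, "in_person", seg, total_duration_s = t0 + trail)
}

# brute-force phrase segmentation oracle: scan the timeline event list
oracle_phrases <- function(sample, min_silence_s = 0.150) {
  phones <- sample$segments[sample$segments$kind == "phone", ]
  sils <- sample$segments[sample$segments$kind == "silence", ]
  if (!nrow(phones)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  span <- c(min(phones$start_s), max(phones$end_s))
  big <- sils[sils$end_s - sils$start_s >= min_silence_s - 1e-9 &
              sils$start_s >= span[1] & sils$end_s <= span[2], ]
  big <- big[order(big$start_s), ]
  cuts <- c(span[1], as.vector(t(big[, c("start_s", "end_s")])), span[2])
  out <- data.frame(start_s = cuts[seq(1, length(cuts) - 1, 2)],
                    end_s = cuts[seq(2, length(cuts), 2)])
  out[out$end_s > out$start_s + 1e-9, , drop = FALSE]
}

# small synthetic cohort configs used in several tests
small_synth_config <- function(tasks = "AMR", n = 4L, ...) {
  nv <- stats::setNames(rep(n, length(tasks)), tasks)
  synthetic_config(n_chr = nv, n_hc = nv, tasks = tasks, ...)
}
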