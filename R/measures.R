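#' Coefficient of variation
#'
#' The scale-free dispersion statistic at the core of the measure battery:
#' sample standard deviation (n-1 denominator) divided by the mean,
#' \eqn{CoV = SD / mean}. Defined here only for strictly positive data
#' (durations, rates, counts), for which it is invariant under rescaling.
#'
#' @param values numeric vector of strictly positive, finite values.
#' @param min_n minimum number of values required; with fewer the function
#'   returns \code{NA} with attribute \code{missing_reason =
#'   "insufficient_tokens"} rather than a value.
#' @return a single non-negative number, or \code{NA} (see \code{min_n}).
#' @examples
#' coefficient_of_variation(c(60, 80, 100))  # 20/80 = 0.25
#' @export
coefficient_of_variation <- function(values, min_n = 2L) {
  if (min_n < 2L) stop("min_n must be at least 2", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("coefficient of variation requires positive finite values; offending index(es): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (length(values) < min_n)
    return(structure(NA_real_, missing_reason = "insufficient_tokens"))
  stats::sd(values) / mean(values)
}

#' Per-trial timing of diadochokinetic speech
#'
#' For an AMR or SMR sample, computes (i) one speech rate per trial window
#' (vowel nuclei in the window / window duration, syllables per second),
#' (ii) the span of every syllable (from the onset of its initial consonant,
#' when adjacent, to the end of its vowel nucleus), and (iii) every
#' intersyllable gap, i.e. the silent interval between consecutive syllables
#' of the same trial (between-trial gaps are excluded).
#'
#' @param sample a [speech_sample()] with task AMR or SMR.
#' @return list with components \code{rates}, \code{syllable_durations},
#'   \code{intersyllable_durations} (numeric vectors).
#' @export
ddk_timing <- function(sample) {
  if (!sample$task %in% c("AMR", "SMR"))
    stop("ddk_timing applies to DDK tasks only (got ", sample$task, ")",
         call. = FALSE)
  tw <- sample$trial_windows
  if (!nrow(tw)) stop("DDK sample has no trial windows", call. = FALSE)
  phones <- phone_segments(sample)
  phones <- phones[order(phones$start_s), , drop = FALSE]
  vow <- is_vowel(phones$label)

  # syllable span: initial consonant onset if the previous phone abuts the
  # vowel, else the vowel itself
  prev_end <- c(-Inf, phones$end_s[-nrow(phones)])
  prev_is_cons <- c(FALSE, !vow[-nrow(phones)])
  syl_start <- ifelse(prev_is_cons & abs(prev_end - phones$start_s) < 1e-6,
                      c(NA, phones$start_s[-nrow(phones)]), phones$start_s)
  nuclei <- data.frame(start_s = syl_start[vow],
                       vowel_start = phones$start_s[vow],
                       end_s = phones$end_s[vow])

  rates <- numeric(0)
  syl_dur <- numeric(0)
  gap_dur <- numeric(0)
  for (i in seq_len(nrow(tw))) {
    dur <- tw$end_s[i] - tw$start_s[i]
    if (dur <= 0) { warning("empty trial window ", i, " skipped", call. = FALSE); next }
    inw <- nuclei[nuclei$vowel_start >= tw$start_s[i] - 1e-9 &
                  nuclei$end_s <= tw$end_s[i] + 1e-9, , drop = FALSE]
    rates <- c(rates, nrow(inw) / dur)
    if (nrow(inw)) {
      syl_dur <- c(syl_dur, inw$end_s - inw$start_s)
      if (nrow(inw) > 1L)
        gap_dur <- c(gap_dur, pmax(inw$start_s[-1] - inw$end_s[-nrow(inw)], 0))
    }
  }
  list(rates = rates, syllable_durations = syl_dur,
       intersyllable_durations = gap_dur[gap_dur > 1e-9])
}

#' Segment connected speech into phrases at silence boundaries
#'
#' A phrase is any maximal spoken interval between silences of at least
#' \code{min_silence_s} (inclusive: a silence of exactly the threshold
#' delimits). Shorter internal silences are absorbed into the phrase; leading
#' and trailing silence is excluded. Phrases and their separating silences
#' interleave and tile the spoken span.
#'
#' @param sample a [speech_sample()] with task READ or SPONT.
#' @param min_silence_s silence threshold in seconds (default 0.150).
#' @return object of class \code{phrase_partition}: list with data frames
#'   \code{phrases} and \code{separating_silences} (columns \code{start_s},
#'   \code{end_s}) and \code{min_silence_s}.
#' @export
segment_phrases <- function(sample, min_silence_s = 0.150) {
  if (!sample$task %in% c("READ", "SPONT"))
    stop("phrase segmentation applies to READ/SPONT tasks only", call. = FALSE)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  phones <- phone_segments(sample)
  if (!nrow(phones))
    return(structure(list(phrases = empty, separating_silences = empty,
                          min_silence_s = min_silence_s),
                     class = "phrase_partition"))
  sil <- silence_segments(sample)
  sil <- sil[sil$end_s - sil$start_s >= min_silence_s - 1e-9, , drop = FALSE]
  span <- c(min(phones$start_s), max(phones$end_s))
  # only silences strictly inside the spoken span separate phrases
  sil <- sil[sil$end_s > span[1] + 1e-9 & sil$start_s < span[2] - 1e-9, , drop = FALSE]
  sil <- sil[order(sil$start_s), , drop = FALSE]
  bounds <- c(span[1], as.vector(rbind(sil$start_s, sil$end_s)), span[2])
  ph_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ph_end <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ph_end - ph_start > 1e-9
  structure(list(phrases = data.frame(start_s = ph_start[keep],
                                      end_s = ph_end[keep]),
                 separating_silences = sil[, c("start_s", "end_s"), drop = FALSE],
                 min_silence_s = min_silence_s),
            class = "phrase_partition")
}

#' Speech rate of each phrase
#'
#' One rate per phrase: vowel nuclei inside the phrase divided by the phrase
#' duration (sub-threshold internal silences count toward the denominator).
#' Phrases containing no syllable nucleus are dropped with a warning.
#'
#' @param partition a [segment_phrases()] result.
#' @param sample the sample the partition came from.
#' @return numeric vector of rates (syllables per second).
#' @export
phrase_rates <- function(partition, sample) {
  phones <- phone_segments(sample)
  nuc <- phones[is_vowel(phones$label), , drop = FALSE]
  ph <- partition$phrases
  rates <- numeric(0)
  for (i in seq_len(nrow(ph))) {
    k <- sum(nuc$start_s >= ph$start_s[i] - 1e-9 & nuc$end_s <= ph$end_s[i] + 1e-9)
    if (k == 0L) {
      warning("phrase ", i, " contains no syllable nucleus; dropped", call. = FALSE)
      next
    }
    rates <- c(rates, k / (ph$end_s[i] - ph$start_s[i]))
  }
  rates
}

#' Pause rate of a connected-speech sample
#'
#' Number of internal silences of at least \code{min_silence_s}, normalized by
#' the total sample duration (events per second).
#'
#' @inheritParams segment_phrases
#' @return pauses per second.
#' @export
pause_rate <- function(sample, min_silence_s = 0.150) {
  if (!sample$task %in% c("READ", "SPONT"))
    stop("pause rate applies to READ/SPONT tasks only", call. = FALSE)
  part <- segment_phrases(sample, min_silence_s)
  nrow(part$separating_silences) / sample$total_duration_s
}

#' Formant dispersion of a vowel token cloud
#'
#' Mean Euclidean distance of the tokens' (F1, F2) points from their centroid,
#' at the 20\% or 50\% timepoint of vowel duration. Larger values indicate a
#' more expanded or more variable vowel space. Tokens missing either formant
#' are dropped (counted in attribute \code{n_dropped}).
#'
#' @param tokens a vowel \code{token_set} (see
#'   [select_stressed_vowel_tokens()]).
#' @param timepoint 20 or 50 (percent of vowel duration).
#' @param min_n minimum usable tokens; below it returns \code{NA} with a
#'   \code{missing_reason} attribute.
#' @return dispersion in Hz.
#' @export
formant_dispersion <- function(tokens, timepoint = 20, min_n = 2L) {
  stopifnot(timepoint %in% c(20, 50))
  f1 <- tokens[[paste0("f1_", timepoint)]]
  f2 <- tokens[[paste0("f2_", timepoint)]]
  ok <- is.finite(f1) & is.finite(f2)
  n_dropped <- sum(!ok)
  f1 <- f1[ok]; f2 <- f2[ok]
  if (!length(f1))
    return(structure(NA_real_, missing_reason = "no_formants", n_dropped = n_dropped))
  if (length(f1) < min_n)
    return(structure(NA_real_, missing_reason = "insufficient_tokens",
                     n_dropped = n_dropped))
  d <- sqrt((f1 - mean(f1))^2 + (f2 - mean(f2))^2)
  structure(mean(d), n_used = length(f1), n_dropped = n_dropped)
}

#' Change in formant dispersion between the 20\% and 50\% timepoints
#'
#' Dispersion at 50\% minus dispersion at 20\%, over the tokens carrying
#' formants at both timepoints. Negative values mean the vowel space
#' contracts toward mid-vowel (typical of read speech); positive values mean
#' it expands.
#'
#' @inheritParams formant_dispersion
#' @return signed change in Hz.
#' @export
dispersion_change <- function(tokens, min_n = 2L) {
  ok <- is.finite(tokens$f1_20) & is.finite(tokens$f2_20) &
    is.finite(tokens$f1_50) & is.finite(tokens$f2_50)
  tk <- tokens[ok, , drop = FALSE]
  d20 <- formant_dispersion(tk, 20, min_n)
  d50 <- formant_dispersion(tk, 50, min_n)
  if (is.na(d20) || is.na(d50))
    return(structure(NA_real_,
                     missing_reason = attr(d20, "missing_reason") %||%
                       attr(d50, "missing_reason")))
  as.numeric(d50) - as.numeric(d20)
}

#' Overlap between vowel categories in formant space
#'
#' Percentage of vowel tokens whose (F1, F2) point at the 20\% timepoint lies
#' strictly closer (Euclidean) to another vowel category's centroid than to
#' its own; ties resolve to the token's own category. 0\% means perfectly
#' separated categories.
#'
#' @param tokens vowel \code{token_set} with 20\% formants.
#' @param categories per-token vowel-category labels (defaults to the
#'   stress-stripped phone label).
#' @param min_n minimum tokens per category for a category to enter.
#' @return percentage in [0, 100], or \code{NA} with \code{missing_reason =
#'   "one_category"} when fewer than two categories qualify.
#' @export
vowel_category_overlap <- function(tokens, categories = NULL, min_n = 2L) {
  if (is.null(categories)) categories <- phone_base(tokens$label)
  ok <- is.finite(tokens$f1_20) & is.finite(tokens$f2_20)
  f1 <- tokens$f1_20[ok]; f2 <- tokens$f2_20[ok]
  categories <- categories[ok]
  tab <- table(categories)
  keep_cats <- names(tab)[tab >= min_n]
  if (length(keep_cats) < 2L)
    return(structure(NA_real_, missing_reason = "one_category"))
  sel <- categories %in% keep_cats
  f1 <- f1[sel]; f2 <- f2[sel]; categories <- categories[sel]
  cent <- cbind(tapply(f1, categories, mean), tapply(f2, categories, mean))
  d2 <- outer(f1, cent[, 1], "-")^2 + outer(f2, cent[, 2], "-")^2
  own <- match(categories, rownames(cent))
  own_d2 <- d2[cbind(seq_along(own), own)]
  other_min <- vapply(seq_along(own),
                      function(i) min(d2[i, -own[i]]), numeric(1))
  # strict inequality with a tolerance: ties go to the own category
  100 * mean(other_min < own_d2 - 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
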