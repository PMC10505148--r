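#' Select syllable-initial prevocalic stop tokens
#'
#' Returns the stop-consonant tokens whose voice-onset-time (VOT) enters the
#' consonant-variability measures: stops of the requested voicing class that
#' are immediately followed by a vowel phone and are syllable-initial. A stop
#' counts as syllable-initial when it is word-initial (its start coincides
#' with a word segment's start), or when the immediately preceding phone-tier
#' event is a vowel, a silence, or nothing (sample start) — a simple
#' onset-maximization proxy. So the "p" of "passerby" or "peanut" is selected
#' while the "p" of "prism" (followed by "r") is not.
#'
#' Each token's VOT is its \code{vot_s} attribute when present (AutoVOT-style
#' input) and otherwise the stop interval's duration (DDK segmentations where
#' the consonant interval is the VOT proxy). Voiced tokens with
#' \code{vot_s <= 0} (prevoicing) are dropped; the number dropped is recorded
#' in the \code{n_prevoiced} attribute. For the DDK tasks (AMR/SMR) only the
#' voiceless class may be requested.
#'
#' @param sample a [speech_sample()].
#' @param voicing \code{"voiceless"} (p,t,k) or \code{"voiced"} (b,d,g).
#' @return an object of class \code{token_set}: the selected phone rows plus a
#'   \code{vot} column, with attributes \code{rule_name}, \code{sample_ref}
#'   and \code{n_prevoiced}.
#' @export
select_stop_tokens <- function(sample, voicing = c("voiceless", "voiced")) {
  voicing <- match.arg(voicing)
  if (voicing == "voiced" && sample$task %in% c("AMR", "SMR"))
    stop("voiced stop selection is not supported for DDK tasks (", sample$task,
         "): DDK consonant analysis is restricted to voiceless stops",
         call. = FALSE)
  phones <- phone_segments(sample)
  if (!nrow(phones)) stop("sample has no phone segments", call. = FALSE)
  phones <- phones[order(phones$start_s), , drop = FALSE]

  sil <- silence_segments(sample)
  ev_start <- c(phones$start_s, sil$start_s)
  ev_end <- c(phones$end_s, sil$end_s)
  ev_label <- c(phones$label, rep("", nrow(sil)))
  ev_is_phone <- c(rep(TRUE, nrow(phones)), rep(FALSE, nrow(sil)))
  ev_idx <- c(seq_len(nrow(phones)), rep(NA_integer_, nrow(sil)))
  o <- order(ev_start)
  ev_start <- ev_start[o]; ev_end <- ev_end[o]; ev_label <- ev_label[o]
  ev_is_phone <- ev_is_phone[o]; ev_idx <- ev_idx[o]

  n <- nrow(phones)
  is_target <- is_stop(phones$label, voicing)
  # next phone must be a vowel starting where the stop ends (adjacent)
  nxt_label <- c(phones$label[-1], NA)
  nxt_start <- c(phones$start_s[-1], NA)
  followed_by_vowel <- !is.na(nxt_label) & is_vowel(nxt_label) &
    abs(nxt_start - phones$end_s) < 1e-6

  # preceding event on the phone+silence timeline
  pos <- match(seq_len(n), ev_idx)
  prev_end <- c(-Inf, ev_end[-length(ev_end)])[pos]
  prev_label <- c(NA_character_, ev_label[-length(ev_label)])[pos]
  prev_phone <- c(FALSE, ev_is_phone[-length(ev_is_phone)])[pos]
  prev_vowel_or_sil <- pos == 1L |                       # sample-initial
    prev_end < ev_start[pos] - 1e-6 |                    # untiled gap
    !prev_phone | is_vowel(ifelse(is.na(prev_label), "", prev_label))

  word_initial <- rep(FALSE, n)
  words <- sample$segments[sample$segments$kind == "word", , drop = FALSE]
  if (nrow(words)) {
    word_initial <- vapply(phones$start_s,
                           function(t) any(abs(words$start_s - t) < 1e-6),
                           logical(1))
  }

  keep <- is_target & followed_by_vowel & (word_initial | prev_vowel_or_sil)
  tokens <- phones[keep, , drop = FALSE]
  tokens$vot <- ifelse(is.na(tokens$vot_s),
                       tokens$end_s - tokens$start_s, tokens$vot_s)
  n_prevoiced <- 0L
  if (voicing == "voiced") {
    drop <- tokens$vot <= 0
    n_prevoiced <- sum(drop)
    tokens <- tokens[!drop, , drop = FALSE]
  }
  new_token_set(tokens, sample, paste0("stop_", voicing),
                n_prevoiced = n_prevoiced)
}

#' Select primary-stressed vowel tokens
#'
#' Returns the vowel tokens used for vowel-duration and formant measures:
#' vowels bearing primary stress (a trailing "1" in the label, or
#' \code{stress == "primary"}). In the DDK tasks every vowel nucleus belongs
#' to a repeated monosyllable and is treated as primary-stressed.
#'
#' @inheritParams select_stop_tokens
#' @return a \code{token_set} of vowel rows with a \code{duration} column.
#' @export
select_stressed_vowel_tokens <- function(sample) {
  phones <- phone_segments(sample)
  vows <- phones[is_vowel(phones$label), , drop = FALSE]
  if (!nrow(vows)) {
    warning("no vowel tokens found in sample ", sample$participant_id, "/",
            sample$task, call. = FALSE)
    tokens <- vows
  } else if (sample$task %in% c("AMR", "SMR")) {
    tokens <- vows
  } else {
    stress <- ifelse(!is.na(vows$stress) & nzchar(vows$stress),
                     vows$stress, label_stress(vows$label))
    tokens <- vows[stress == "primary", , drop = FALSE]
  }
  if (nrow(tokens)) tokens$duration <- tokens$end_s - tokens$start_s
  else tokens$duration <- numeric(0)
  new_token_set(tokens, sample, "stressed_vowel")
}

new_token_set <- function(tokens, sample, rule_name, n_prevoiced = 0L) {
  rownames(tokens) <- NULL
  structure(tokens,
            rule_name = rule_name,
            sample_ref = c(participant_id = sample$participant_id,
                           task = sample$task, modality = sample$modality),
            n_prevoiced = n_prevoiced,
            class = c("token_set", "data.frame"))
}
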