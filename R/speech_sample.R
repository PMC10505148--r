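#' Construct a speech sample from labeled time intervals
#'
#' A \code{speech_sample} holds every time-aligned segment of one participant
#' performing one speech task in one testing modality, together with the trial
#' windows of diadochokinetic (DDK) tasks. Segments live in a data frame with
#' one row per labeled interval; intervals are half-open \code{[start_s,
#' end_s)} in seconds from the start of the recording.
#'
#' @param participant_id single character id.
#' @param task one of \code{"AMR"}, \code{"SMR"}, \code{"READ"}, \code{"SPONT"}.
#'   AMR/SMR are the diadochokinetic tasks (single repeated syllable vs.
#'   repeated three-syllable sequence); READ is a read passage; SPONT is a
#'   spontaneous sample.
#' @param modality \code{"in_person"} or \code{"remote"}.
#' @param segments data frame with columns \code{label}, \code{kind} (one of
#'   \code{phone}, \code{word}, \code{trial}, \code{silence}), \code{start_s},
#'   \code{end_s}, and optionally \code{vot_s} (voice-onset-time of stop
#'   tokens, seconds), \code{f1_20}, \code{f2_20}, \code{f1_50}, \code{f2_50}
#'   (vowel formants in Hz at 20\% and 50\% of vowel duration) and
#'   \code{stress} (\code{primary}/\code{nonprimary}/\code{none}).
#' @param trial_windows data frame with columns \code{start_s}, \code{end_s};
#'   required (possibly incomplete) for AMR/SMR, empty otherwise. A complete
#'   AMR sample has 12 windows and a complete SMR sample 20; incomplete
#'   samples are accepted with a warning.
#' @param total_duration_s total recording duration in seconds; defaults to
#'   the largest segment end time.
#' @return an object of class \code{speech_sample}.
#' @export
speech_sample <- function(participant_id, task, modality, segments,
                          trial_windows = NULL, total_duration_s = NULL) {
  task <- match.arg(task, c("AMR", "SMR", "READ", "SPONT"))
  modality <- match.arg(modality, c("in_person", "remote"))
  segments <- normalize_segments(segments)
  validate_segments(segments)

  if (is.null(trial_windows)) {
    trial_windows <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  trial_windows <- as.data.frame(trial_windows)[, c("start_s", "end_s"), drop = FALSE]
  if (task %in% c("AMR", "SMR")) {
    expected <- if (task == "AMR") 12L else 20L
    if (nrow(trial_windows) == 0L)
      stop("task ", task, " requires trial windows", call. = FALSE)
    if (nrow(trial_windows) != expected)
      warning("incomplete ", task, " sample: ", nrow(trial_windows),
              " trial windows (expected ", expected, ")", call. = FALSE)
  }

  if (is.null(total_duration_s)) {
    total_duration_s <- if (nrow(segments)) max(segments$end_s) else 0
  }
  total_duration_s <- unname(as.numeric(total_duration_s))

  structure(
    list(participant_id = as.character(participant_id),
         task = task, modality = modality,
         segments = segments,
         trial_windows = trial_windows,
         total_duration_s = total_duration_s),
    class = "speech_sample")
}

# coerce a partial segments frame to the full column set, ordered by kind/start
normalize_segments <- function(segments) {
  segments <- as.data.frame(segments)
  n <- nrow(segments)
  opt_num <- c("vot_s", "f1_20", "f2_20", "f1_50", "f2_50")
  for (col in opt_num) if (is.null(segments[[col]])) segments[[col]] <- rep(NA_real_, n)
  if (is.null(segments$stress)) segments$stress <- rep(NA_character_, n)
  segments$label <- as.character(segments$label)
  segments$kind <- as.character(segments$kind)
  for (col in c("start_s", "end_s", opt_num)) segments[[col]] <- as.numeric(segments[[col]])
  segments <- segments[, c("label", "kind", "start_s", "end_s", opt_num, "stress")]
  segments[order(segments$kind, segments$start_s), , drop = FALSE]
}

validate_segments <- function(segments) {
  if (!nrow(segments)) return(invisible(TRUE))
  bad_kind <- setdiff(unique(segments$kind), c("phone", "word", "trial", "silence"))
  if (length(bad_kind))
    stop("unknown segment kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  nonpos <- which(!(segments$end_s > segments$start_s))
  if (length(nonpos))
    stop("segments with end_s <= start_s at rows ",
         paste(utils::head(nonpos, 5), collapse = ", "), call. = FALSE)
  if (any(!is.finite(segments$start_s)) || any(!is.finite(segments$end_s)))
    stop("non-finite segment times", call. = FALSE)
  vot <- segments$vot_s
  dur <- segments$end_s - segments$start_s
  # half-open intervals: vot must fit inside its phone interval
  bad_vot <- which(!is.na(vot) & vot > dur + 1e-9)
  if (length(bad_vot))
    stop("vot_s exceeds interval duration at rows ",
         paste(utils::head(bad_vot, 5), collapse = ", "), call. = FALSE)
  # no overlap within a tier kind
  for (k in unique(segments$kind)) {
    sk <- segments[segments$kind == k, , drop = FALSE]
    sk <- sk[order(sk$start_s), , drop = FALSE]
    if (nrow(sk) > 1L) {
      ov <- which(sk$start_s[-1] < sk$end_s[-nrow(sk)] - 1e-9)
      if (length(ov))
        stop("overlapping ", k, " intervals starting at t = ",
             paste(signif(sk$start_s[ov + 1L], 6), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.speech_sample <- function(x, ...) {
  counts <- table(factor(x$segments$kind, c("phone", "word", "trial", "silence")))
  cat(sprintf("<speech_sample> %s / %s / %s\n", x$participant_id, x$task, x$modality))
  cat(sprintf("  %.2f s total; %d phones, %d words, %d trials, %d silences; %d trial windows\n",
              x$total_duration_s, counts[["phone"]], counts[["word"]],
              counts[["trial"]], counts[["silence"]], nrow(x$trial_windows)))
  invisible(x)
}

phone_segments <- function(sample) {
  sample$segments[sample$segments$kind == "phone", , drop = FALSE]
}

silence_segments <- function(sample) {
  sample$segments[sample$segments$kind == "silence", , drop = FALSE]
}
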