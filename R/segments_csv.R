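#' Read and write segment tables as CSV
#'
#' The segment CSV schema has one row per interval with columns
#' \code{participant_id, task, modality, kind, label, start_s, end_s, vot_s,
#' f1_20, f2_20, f1_50, f2_50, stress} (extra columns are ignored on read;
#' optional cells are empty). \code{read_segments_csv} groups rows into one
#' [speech_sample()] per (participant, task, modality); writing and re-reading
#' a sample is the identity on every field.
#'
#' @param path CSV path.
#' @param trial_windows_from if \code{"trial_segments"} (default), trial
#'   windows of DDK samples are rebuilt from rows with \code{kind == "trial"}.
#' @return \code{read_segments_csv}: a list of [speech_sample()] objects.
#' @export
read_segments_csv <- function(path, trial_windows_from = "trial_segments") {
  required <- c("participant_id", "task", "modality", "kind", "label",
                "start_s", "end_s", "vot_s", "f1_20", "f2_20", "f1_50",
                "f2_50", "stress")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("segment CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, required, drop = FALSE]
  for (col in c("start_s", "end_s", "vot_s", "f1_20", "f2_20", "f1_50", "f2_50")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric ", col, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    df[[col]] <- num
  }
  df$stress[!nzchar(df$stress)] <- NA_character_

  key <- interaction(df$participant_id, df$task, df$modality, drop = TRUE)
  lapply(split(df, key), function(g) {
    seg <- g[, c("label", "kind", "start_s", "end_s", "vot_s",
                 "f1_20", "f2_20", "f1_50", "f2_50", "stress"), drop = FALSE]
    tw <- NULL
    if (identical(trial_windows_from, "trial_segments")) {
      tr <- seg[seg$kind == "trial", , drop = FALSE]
      if (nrow(tr)) tw <- data.frame(start_s = tr$start_s, end_s = tr$end_s)
    }
    speech_sample(g$participant_id[1], g$task[1], g$modality[1], seg,
                  trial_windows = tw)
  })
}

#' @rdname read_segments_csv
#' @param samples a [speech_sample()] or list of them.
#' @export
write_segments_csv <- function(samples, path) {
  if (inherits(samples, "speech_sample")) samples <- list(samples)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  rows <- lapply(samples, function(s) {
    seg <- s$segments
    data.frame(participant_id = s$participant_id, task = s$task,
               modality = s$modality, kind = seg$kind, label = seg$label,
               start_s = fmt(seg$start_s), end_s = fmt(seg$end_s),
               vot_s = fmt(seg$vot_s),
               f1_20 = fmt(seg$f1_20), f2_20 = fmt(seg$f2_20),
               f1_50 = fmt(seg$f1_50), f2_50 = fmt(seg$f2_50),
               stress = ifelse(is.na(seg$stress), "", seg$stress),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
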