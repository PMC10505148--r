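#' Measure battery configuration
#'
#' @param min_silence_s pause/phrase silence threshold in seconds (0.150:
#'   phrases are spoken intervals between silences of at least 150 ms).
#' @param min_n minimum tokens for a CoV/dispersion measure (default 5, a
#'   stability floor).
#' @param log_epsilon offset used when log-transforming exact zeros (overlap
#'   and pause measures can be 0): zeros become \code{log(epsilon)}.
#' @param measures optional character vector restricting which measures are
#'   computed (names as in [measure_applicability()]).
#' @return a list of class \code{sv_config}.
#' @export
measure_config <- function(min_silence_s = 0.150, min_n = 5L,
                           log_epsilon = 1e-3, measures = NULL) {
  stopifnot(min_silence_s > 0, min_n >= 2, log_epsilon > 0)
  structure(list(min_silence_s = min_silence_s, min_n = as.integer(min_n),
                 log_epsilon = log_epsilon, measures = measures),
            class = "sv_config")
}

#' Which measure applies to which speech task
#'
#' The battery comprises ten measures; blank task cells of the battery are
#' never computed. Durational measures (the CoV-of-duration family) are the
#' ones whose group analyses adjust for averaged speech rate.
#'
#' @return data frame with columns \code{measure}, \code{task},
#'   \code{durational}.
#' @export
measure_applicability <- function() {
  if (!is.null(.sv_cache$app)) return(.sv_cache$app)
  all4 <- c("AMR", "SMR", "READ", "SPONT")
  conn <- c("READ", "SPONT")
  ddk <- c("AMR", "SMR")
  .sv_cache$app <- rbind(
    data.frame(measure = "voiceless_vot_cov", task = all4, durational = TRUE),
    data.frame(measure = "voiced_vot_cov", task = conn, durational = TRUE),
    data.frame(measure = "speech_rate_cov", task = all4, durational = FALSE),
    data.frame(measure = "vowel_duration_cov", task = all4, durational = TRUE),
    data.frame(measure = "formant_dispersion_20", task = all4, durational = FALSE),
    data.frame(measure = "formant_dispersion_change_20_50", task = all4, durational = FALSE),
    data.frame(measure = "vowel_category_overlap", task = conn, durational = FALSE),
    data.frame(measure = "syllable_duration_cov", task = ddk, durational = TRUE),
    data.frame(measure = "intersyllable_duration_cov", task = ddk, durational = TRUE),
    data.frame(measure = "pause_rate", task = conn, durational = FALSE))
  .sv_cache$app
}

.sv_cache <- new.env(parent = emptyenv())

sv_measure_names <- function() unique(measure_applicability()$measure)

# one participant x task: compute every applicable measure
compute_sample_measures <- function(sample, config = measure_config()) {
  app <- measure_applicability()
  app <- app[app$task == sample$task, , drop = FALSE]
  if (!is.null(config$measures))
    app <- app[app$measure %in% config$measures, , drop = FALSE]
  meas <- app$measure

  vot_tokens <- if ("voiceless_vot_cov" %in% meas)
    try(select_stop_tokens(sample, "voiceless"), silent = TRUE) else NULL
  vowel_tokens <- if (any(c("vowel_duration_cov", "formant_dispersion_20",
                            "formant_dispersion_change_20_50",
                            "vowel_category_overlap") %in% meas))
    suppressWarnings(select_stressed_vowel_tokens(sample)) else NULL
  ddk <- if (sample$task %in% c("AMR", "SMR")) ddk_timing(sample) else NULL
  rates <- if (!is.null(ddk)) ddk$rates else {
    part <- segment_phrases(sample, config$min_silence_s)
    suppressWarnings(phrase_rates(part, sample))
  }
  mean_rate <- if (length(rates)) mean(rates) else NA_real_

  cov_or_miss <- function(values) {
    if (!length(values))
      return(list(raw = NA_real_, reason = "no_tokens", n = 0L))
    v <- coefficient_of_variation(values, min_n = config$min_n)
    list(raw = as.numeric(v),
         reason = attr(v, "missing_reason") %||% NA_character_,
         n = length(values))
  }

  one <- function(measure) {
    res <- switch(
      measure,
      voiceless_vot_cov = {
        if (inherits(vot_tokens, "try-error"))
          list(raw = NA_real_, reason = "no_tokens", n = 0L)
        else cov_or_miss(vot_tokens$vot)
      },
      voiced_vot_cov = {
        tk <- try(select_stop_tokens(sample, "voiced"), silent = TRUE)
        if (inherits(tk, "try-error")) list(raw = NA_real_, reason = "no_tokens", n = 0L)
        else cov_or_miss(tk$vot)
      },
      speech_rate_cov = cov_or_miss(rates),
      vowel_duration_cov = cov_or_miss(vowel_tokens$duration),
      formant_dispersion_20 = {
        v <- formant_dispersion(vowel_tokens, 20, config$min_n)
        list(raw = as.numeric(v), reason = attr(v, "missing_reason") %||% NA_character_,
             n = attr(v, "n_used") %||% 0L)
      },
      formant_dispersion_change_20_50 = {
        v <- dispersion_change(vowel_tokens, config$min_n)
        list(raw = as.numeric(v), reason = attr(v, "missing_reason") %||% NA_character_,
             n = nrow(vowel_tokens))
      },
      vowel_category_overlap = {
        v <- vowel_category_overlap(vowel_tokens, min_n = config$min_n)
        list(raw = as.numeric(v), reason = attr(v, "missing_reason") %||% NA_character_,
             n = nrow(vowel_tokens))
      },
      syllable_duration_cov = cov_or_miss(ddk$syllable_durations),
      intersyllable_duration_cov = cov_or_miss(ddk$intersyllable_durations),
      pause_rate = list(raw = pause_rate(sample, config$min_silence_s),
                        reason = NA_character_, n = NA_integer_),
      stop("unknown measure: ", measure))
    res
  }
  results <- lapply(meas, one)
  data.frame(participant_id = sample$participant_id, task = sample$task,
             modality = sample$modality, measure = meas,
             raw = vapply(results, function(r) as.numeric(r$raw), numeric(1)),
             log = NA_real_,
             n_tokens = vapply(results, function(r)
               as.integer(r$n %||% NA_integer_), integer(1)),
             missing_reason = vapply(results, function(r)
               as.character(r$reason %||% NA_character_), character(1)),
             mean_rate = mean_rate, stringsAsFactors = FALSE)
}

#' Compute the measure battery for a collection of samples
#'
#' Applies every task-applicable measure to each sample, records token counts
#' and missingness reasons (a failed measure never aborts the table), attaches
#' natural-log values via [log_transform_measures()], and carries each
#' sample's averaged speech rate (the covariate of the durational group
#' analyses) in the \code{mean_rate} column.
#'
#' @param samples a list of [speech_sample()] objects.
#' @param config a [measure_config()].
#' @return a data frame of class \code{measure_table} with columns
#'   \code{participant_id, task, modality, measure, raw, log, n_tokens,
#'   missing_reason, mean_rate}.
#' @export
compute_measure_table <- function(samples, config = measure_config()) {
  if (inherits(samples, "speech_sample")) samples <- list(samples)
  rows <- lapply(samples, compute_sample_measures, config = config)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("measure_table", "data.frame")
  log_transform_measures(tab, epsilon = config$log_epsilon)
}

#' Natural-log transform of the measure table
#'
#' Variability measures are right-skewed (bounded below at 0), so analyses run
#' on the natural log. Exact zeros become \code{log(epsilon)}; negative raw
#' values (possible only for the signed dispersion-change measure) have no log
#' and keep \code{NA}. Raw values are untouched.
#'
#' @param table a \code{measure_table}.
#' @param epsilon zero offset on the measure's natural scale.
#' @return the table with its \code{log} column populated.
#' @export
log_transform_measures <- function(table, epsilon = 1e-3) {
  raw <- table$raw
  lg <- rep(NA_real_, length(raw))
  lg[!is.na(raw) & raw > 0] <- log(raw[!is.na(raw) & raw > 0])
  lg[!is.na(raw) & raw == 0] <- log(epsilon)
  table$log <- lg
  table
}

#' Write / read a measure table as tidy CSV
#'
#' Numeric cells are written with a fixed \code{\%.10g} format so identical
#' results are byte-identical across platforms.
#'
#' @param table a \code{measure_table}.
#' @param path CSV path.
#' @export
write_measure_csv <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  out <- data.frame(participant_id = table$participant_id, task = table$task,
                    modality = table$modality, measure = table$measure,
                    raw = fmt(table$raw), log = fmt(table$log),
                    n_tokens = ifelse(is.na(table$n_tokens), "", table$n_tokens),
                    missing_reason = ifelse(is.na(table$missing_reason), "",
                                            table$missing_reason),
                    mean_rate = fmt(table$mean_rate),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_measure_csv
#' @export
read_measure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in c("raw", "log", "mean_rate"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$n_tokens <- suppressWarnings(as.integer(df$n_tokens))
  df$missing_reason[!nzchar(df$missing_reason)] <- NA_character_
  class(df) <- c("measure_table", "data.frame")
  df
}

#' @export
print.measure_table <- function(x, ...) {
  cat(sprintf("<measure_table> %d rows; %d participants; tasks: %s\n",
              nrow(x), length(unique(x$participant_id)),
              paste(sort(unique(x$task)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
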