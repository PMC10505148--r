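#' Read a Praat TextGrid into a speech sample
#'
#' Parses a long-format Praat TextGrid and maps its interval tiers onto the
#' segment kinds the measure battery consumes. Intervals with empty or
#' whitespace-only labels on the phone tier are treated as silences, as are
#' gaps between labeled intervals, so that phone-covered time plus silence
#' time tiles the recording.
#'
#' @param path path to a long-format TextGrid (UTF-8; UTF-16 is detected and
#'   re-read).
#' @param tier_map named character vector mapping roles to tier names, e.g.
#'   \code{c(phone = "phones", word = "words", trial = "trials")}. At least a
#'   \code{phone} entry is required; \code{word} and \code{trial} are optional.
#' @param participant_id,task,modality sample metadata (not stored in the
#'   TextGrid itself).
#' @return a [speech_sample()].
#' @export
read_textgrid <- function(path, tier_map = c(phone = "phones"),
                          participant_id = "unknown", task = "READ",
                          modality = "in_person") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- read_textgrid_lines(path)
  tg <- parse_textgrid_long(lines, path)
  if (!"phone" %in% names(tier_map))
    stop("tier_map must name a phone tier", call. = FALSE)

  seg_list <- list()
  for (role in intersect(names(tier_map), c("phone", "word", "trial"))) {
    tier_name <- tier_map[[role]]
    tier <- tg$tiers[[tier_name]]
    if (is.null(tier))
      stop("tier '", tier_name, "' (role ", role, ") not present in ", path,
           call. = FALSE)
    iv <- tier$intervals
    blank <- !nzchar(trimws(iv$text))
    if (role == "phone") {
      # labeled intervals are phones; blanks and gaps become silences
      phones <- iv[!blank, , drop = FALSE]
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        label = phones$text, kind = "phone",
        start_s = phones$xmin, end_s = phones$xmax,
        stringsAsFactors = FALSE)
      sil <- tier_gaps(iv, blank, tg$xmin, tg$xmax)
      if (nrow(sil))
        seg_list[[length(seg_list) + 1L]] <- data.frame(
          label = "", kind = "silence",
          start_s = sil$start_s, end_s = sil$end_s,
          stringsAsFactors = FALSE)
    } else {
      keep <- iv[!blank, , drop = FALSE]
      if (nrow(keep))
        seg_list[[length(seg_list) + 1L]] <- data.frame(
          label = keep$text, kind = role,
          start_s = keep$xmin, end_s = keep$xmax,
          stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_list)

  trial_windows <- NULL
  if ("trial" %in% names(tier_map)) {
    tw <- segments[segments$kind == "trial", , drop = FALSE]
    trial_windows <- data.frame(start_s = tw$start_s, end_s = tw$end_s)
  }
  speech_sample(participant_id, task, modality, segments,
                trial_windows = trial_windows, total_duration_s = tg$xmax)
}

# blank intervals plus inter-interval gaps, merged where adjacent
tier_gaps <- function(iv, blank, xmin, xmax) {
  spans <- iv[blank, c("xmin", "xmax"), drop = FALSE]
  lab <- iv[!blank, , drop = FALSE]
  lab <- lab[order(lab$xmin), , drop = FALSE]
  bounds <- c(xmin, as.vector(rbind(lab$xmin, lab$xmax)), xmax)
  gap_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
  gap_end <- bounds[seq(2, length(bounds), by = 2)]
  gaps <- data.frame(start_s = gap_start, end_s = gap_end)
  gaps <- gaps[gaps$end_s - gaps$start_s > 1e-9, , drop = FALSE]
  gaps
}

read_textgrid_lines <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # UTF-16 fallback: Praat writes a BOM
  if (length(raw) >= 2 &&
      ((raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) ||
       (raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)))) {
    con <- file(path, encoding = "UTF-16")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  strsplit(txt, "\r?\n")[[1]]
}

parse_textgrid_long <- function(lines, path = "<textgrid>") {
  get_num <- function(i) {
    m <- regmatches(lines[i], regexpr("-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?\\s*$", lines[i]))
    if (!length(m)) stop("malformed TextGrid at line ", i, " of ", path,
                         ": expected a number in '", lines[i], "'", call. = FALSE)
    as.numeric(m)
  }
  get_str <- function(i) {
    m <- regmatches(lines[i], regexpr('"[^"]*"', lines[i]))
    if (!length(m)) stop("malformed TextGrid at line ", i, " of ", path,
                         ": expected a quoted string in '", lines[i], "'", call. = FALSE)
    substr(m, 2, nchar(m) - 1L)
  }
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))])))
    stop("malformed TextGrid (missing ooTextFile header) in ", path, call. = FALSE)
  xmin_i <- grep("^\\s*xmin", lines)[1]
  xmax_i <- grep("^\\s*xmax", lines)[1]
  g_xmin <- get_num(xmin_i); g_xmax <- get_num(xmax_i)

  item_idx <- grep("^\\s*item\\s*\\[[0-9]+\\]", lines)
  tiers <- list()
  for (j in seq_along(item_idx)) {
    lo <- item_idx[j]
    hi <- if (j < length(item_idx)) item_idx[j + 1L] - 1L else length(lines)
    block <- lo:hi
    cls_i <- block[grep("^\\s*class", lines[block])[1]]
    if (is.na(cls_i)) next
    if (get_str(cls_i) != "IntervalTier") next
    name_i <- block[grep("^\\s*name", lines[block])[1]]
    tier_name <- get_str(name_i)
    xmin_is <- block[grep("^\\s*xmin", lines[block])]
    xmax_is <- block[grep("^\\s*xmax", lines[block])]
    text_is <- block[grep("^\\s*text", lines[block])]
    # first xmin/xmax of the block describe the tier itself
    xmins <- vapply(xmin_is[-1], get_num, numeric(1))
    xmaxs <- vapply(xmax_is[-1], get_num, numeric(1))
    texts <- vapply(text_is, get_str, character(1))
    if (length(xmins) != length(texts))
      stop("malformed TextGrid tier '", tier_name, "' in ", path,
           ": ", length(xmins), " xmin lines vs ", length(texts),
           " text lines", call. = FALSE)
    iv <- data.frame(xmin = xmins, xmax = xmaxs, text = texts,
                     stringsAsFactors = FALSE)
    if (nrow(iv) > 1L) {
      iv <- iv[order(iv$xmin), , drop = FALSE]
      ov <- which(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-9)
      if (length(ov))
        stop("overlapping intervals in tier '", tier_name, "' at t = ",
             paste(signif(iv$xmin[ov + 1L], 6), collapse = ", "), call. = FALSE)
    }
    tiers[[tier_name]] <- list(name = tier_name, intervals = iv)
  }
  list(xmin = g_xmin, xmax = g_xmax, tiers = tiers)
}

#' Write a speech sample as a long-format Praat TextGrid
#'
#' Emits one interval tier per segment kind present (phones, words, trials).
#' Silence segments are written as empty-label intervals on the phone tier so
#' that a read/write round trip reproduces the segment list. Times are written
#' with 17 significant digits, which round-trips IEEE doubles exactly.
#'
#' @param sample a [speech_sample()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_textgrid <- function(sample, path) {
  fmt <- function(x) sprintf("%.17g", x)
  xmax <- sample$total_duration_s

  tier_block <- function(n, name, iv) {
    out <- c(sprintf("    item [%d]:", n),
             '        class = "IntervalTier"',
             sprintf('        name = "%s"', name),
             sprintf("        xmin = %s", fmt(0)),
             sprintf("        xmax = %s", fmt(xmax)),
             sprintf("        intervals: size = %d", nrow(iv)))
    for (i in seq_len(nrow(iv))) {
      out <- c(out,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %s", fmt(iv$start_s[i])),
               sprintf("            xmax = %s", fmt(iv$end_s[i])),
               sprintf('            text = "%s"', iv$label[i]))
    }
    out
  }

  seg <- sample$segments
  phones <- seg[seg$kind %in% c("phone", "silence"), , drop = FALSE]
  phones <- phones[order(phones$start_s), , drop = FALSE]
  phones$label[phones$kind == "silence"] <- ""
  tiers <- list(list(name = "phones", iv = phones))
  words <- seg[seg$kind == "word", , drop = FALSE]
  if (nrow(words)) tiers <- c(tiers, list(list(name = "words", iv = words)))
  trials <- seg[seg$kind == "trial", , drop = FALSE]
  if (nrow(trials) == 0L && nrow(sample$trial_windows)) {
    trials <- data.frame(label = sprintf("trial%02d", seq_len(nrow(sample$trial_windows))),
                         start_s = sample$trial_windows$start_s,
                         end_s = sample$trial_windows$end_s)
  }
  if (nrow(trials)) tiers <- c(tiers, list(list(name = "trials", iv = trials)))

  lines <- c('File type = "ooTextFile"',
             'Object class = "TextGrid"',
             "",
             sprintf("xmin = %s", fmt(0)),
             sprintf("xmax = %s", fmt(xmax)),
             "tiers? <exists>",
             sprintf("size = %d", length(tiers)),
             "item []:")
  for (i in seq_along(tiers))
    lines <- c(lines, tier_block(i, tiers[[i]]$name, tiers[[i]]$iv))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
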