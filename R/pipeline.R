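#' Read / write the participant covariate table
#'
#' Columns: \code{participant_id, group, modality, age, sex, race, ethnicity,
#' first_language}, SIPS totals (\code{sips_positive_total},
#' \code{sips_negative_total}, \code{sips_disorganized_total},
#' \code{sips_g3}), three tapping trial counts per hand (\code{tap_dom_1..3},
#' \code{tap_nd_1..3}), and \code{sips_rc_risk}. On read, the per-hand
#' tapping CoVs are (re)computed with [finger_tapping_cov()].
#'
#' @param path CSV path.
#' @export
read_participants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "modality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("participant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tap_cols <- function(prefix) paste0(prefix, 1:3)
  if (all(tap_cols("tap_dom_") %in% names(df)))
    df$tap_cov_dominant <- apply(df[, tap_cols("tap_dom_")], 1,
                                 function(x) as.numeric(finger_tapping_cov(x)))
  if (all(tap_cols("tap_nd_") %in% names(df)))
    df$tap_cov_nondominant <- apply(df[, tap_cols("tap_nd_")], 1,
                                    function(x) as.numeric(finger_tapping_cov(x)))
  df
}

#' @rdname read_participants_csv
#' @param participants participant data frame.
#' @export
write_participants_csv <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

sv_validation_fields <- function() {
  c("sips_positive_total", "sips_negative_total", "sips_disorganized_total",
    "sips_g3", "tap_cov_dominant", "tap_cov_nondominant", "sips_rc_risk")
}

#' Group-difference analysis over the whole measure table
#'
#' Runs [fit_group_difference()] for every measure x task cell present in the
#' table and summarizes each cell with per-group descriptives of the raw
#' measure plus the regression test of the log measure.
#'
#' @inheritParams fit_group_difference
#' @return data frame with one row per measure x task: group means/SDs,
#'   \code{beta}, \code{se}, \code{t}, \code{p}, \code{n}.
#' @export
analyze_group_differences <- function(table, participants) {
  cells <- unique(table[, c("measure", "task")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- cells$measure[i]; t <- cells$task[i]
    d <- measure_frame(table, participants, m, t)
    desc <- function(g) {
      x <- d$raw[d$group == g & !is.na(d$raw)]
      c(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
    chr <- desc("CHR"); hc <- desc("HC")
    fit <- try(fit_group_difference(table, participants, m, t), silent = TRUE)
    fail <- inherits(fit, "try-error")
    data.frame(measure = m, task = t,
               chr_mean = chr[["mean"]], chr_sd = chr[["sd"]],
               chr_n = chr[["n"]],
               hc_mean = hc[["mean"]], hc_sd = hc[["sd"]], hc_n = hc[["n"]],
               beta = if (fail) NA_real_ else fit$beta,
               se = if (fail) NA_real_ else fit$se,
               t = if (fail) NA_real_ else fit$t,
               p = if (fail) NA_real_ else fit$p,
               n = if (fail) NA_integer_ else fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validity grid for significant measures
#'
#' Implements the gating rule of the analysis plan: only measures whose group
#' comparison is significant (p < alpha) are correlated, within the clinical
#' group, with each clinical/motor/risk validation field.
#'
#' @param group_results output of [analyze_group_differences()].
#' @inheritParams fit_group_difference
#' @param fields validation fields to correlate.
#' @param alpha significance gate.
#' @return data frame with columns \code{measure, task, field, r, p, n}.
#' @export
analyze_validity <- function(table, participants, group_results,
                             fields = sv_validation_fields(), alpha = 0.05) {
  sig <- group_results[!is.na(group_results$p) & group_results$p < alpha, ,
                       drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    for (f in intersect(fields, names(participants))) {
      res <- try(fit_validity_correlation(table, participants, sig$measure[i],
                                          sig$task[i], f), silent = TRUE)
      if (inherits(res, "try-error")) next
      rows[[length(rows) + 1L]] <- data.frame(
        measure = sig$measure[i], task = sig$task[i], field = f,
        r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(measure = character(0), task = character(0),
                      field = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0)))
  do.call(rbind, rows)
}

#' Render a group-summary grid shaped like a descriptives table
#'
#' One row block per measure with CHR / HC / p lines and cells formatted
#' \code{"mean (SD)"}; measure x task combinations that are not part of the
#' battery stay blank.
#'
#' @param group_results output of [analyze_group_differences()].
#' @return character-matrix-like data frame with a \code{measure} and
#'   \code{row} column plus one column per task.
#' @export
render_group_table <- function(group_results) {
  tasks <- c("AMR", "SMR", "READ", "SPONT")
  if (!nrow(group_results)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 6), c("measure", "row", tasks)))
    return(out)
  }
  fmt <- function(m, s) sprintf("%.4g (%.4g)", m, s)
  rows <- list()
  for (meas in unique(group_results$measure)) {
    sub <- group_results[group_results$measure == meas, , drop = FALSE]
    line <- function(what) {
      vals <- vapply(tasks, function(t) {
        r <- sub[sub$task == t, , drop = FALSE]
        if (!nrow(r)) return("")
        switch(what,
               CHR = fmt(r$chr_mean, r$chr_sd),
               HC = fmt(r$hc_mean, r$hc_sd),
               p = sprintf("%.3g", r$p))
      }, character(1))
      c(list(measure = meas, row = what), as.list(vals))
    }
    rows <- c(rows, list(line("CHR"), line("HC"), line("p")))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- c("measure", "row", tasks)
  out
}

#' Parse a rendered "mean (SD)" group table back to numbers
#'
#' Inverse of [render_group_table()] for the CHR/HC rows; used to check the
#' rendered grid is faithful.
#'
#' @param rendered output of [render_group_table()] (or its CSV re-read).
#' @export
parse_group_table <- function(rendered) {
  tasks <- c("AMR", "SMR", "READ", "SPONT")
  rows <- list()
  for (i in seq_len(nrow(rendered))) {
    if (!rendered$row[i] %in% c("CHR", "HC")) next
    for (t in tasks) {
      cell <- rendered[[t]][i]
      if (!nzchar(cell)) next
      m <- regmatches(cell, regexec("^(-?[0-9.eE+-]+) \\((-?[0-9.eE+-]+)\\)$", cell))[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = rendered$measure[i], task = t, group = rendered$row[i],
        mean = as.numeric(m[2]), sd = as.numeric(m[3]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' One-command orchestration: simulate a cohort (or ingest segment +
#' participant tables), compute the measure battery, run the group,
#' validity, and modality analyses plus the power report, and write all
#' outputs to \code{out_dir}: \code{measures.csv}, \code{participants.csv},
#' \code{group_summary.csv}, \code{group_table.csv}, \code{validity_grid.csv},
#' \code{modality.csv}, \code{power.txt}, \code{run_log.json}, and
#' \code{MANIFEST}. Fully deterministic given (config, seed).
#'
#' @param mode \code{"simulate"} or \code{"ingest"}.
#' @param out_dir output directory (created if needed).
#' @param seed master seed for simulate mode.
#' @param synth_config an [synthetic_config()] (simulate mode).
#' @param segments_csv,participants_csv input paths (ingest mode).
#' @param config a [measure_config()].
#' @param alpha significance level used throughout.
#' @param power_r,power_power convention for the power report.
#' @return invisible list with all intermediate results.
#' @export
run_pipeline <- function(mode = c("simulate", "ingest"), out_dir,
                         seed = 1L, synth_config = synthetic_config(),
                         segments_csv = NULL, participants_csv = NULL,
                         config = measure_config(), alpha = 0.05,
                         power_r = 0.37, power_power = 0.80) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(stage) {
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] done")
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }

  if (mode == "simulate") {
    cohort <- generate_cohort(synth_config, seed = seed, detail = "segments")
    participants <- cohort$participants
    samples <- cohort$samples
  } else {
    if (is.null(segments_csv) || is.null(participants_csv))
      stop("ingest mode needs segments_csv and participants_csv", call. = FALSE)
    samples <- read_segments_csv(segments_csv)
    participants <- read_participants_csv(participants_csv)
  }
  note("input")

  measures <- compute_measure_table(samples, config)
  write_measure_csv(measures, file.path(out_dir, "measures.csv"))
  write_participants_csv(participants, file.path(out_dir, "participants.csv"))
  note("measures")

  group_results <- analyze_group_differences(measures, participants)
  utils::write.csv(group_results, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(render_group_table(group_results),
                   file.path(out_dir, "group_table.csv"), row.names = FALSE)
  note("group")

  validity <- analyze_validity(measures, participants, group_results,
                               alpha = alpha)
  utils::write.csv(validity, file.path(out_dir, "validity_grid.csv"),
                   row.names = FALSE)
  note("validity")

  modality <- NULL
  if (length(unique(participants$modality)) == 2L) {
    sig <- group_results[!is.na(group_results$p) & group_results$p < alpha, ,
                         drop = FALSE]
    mrows <- list()
    for (i in seq_len(nrow(sig))) {
      res <- suppressWarnings(
        modality_stratified_analysis(measures, participants, sig$measure[i],
                                     sig$task[i]))
      row <- data.frame(measure = sig$measure[i], task = sig$task[i],
                        stringsAsFactors = FALSE)
      for (part in c("in_person", "remote", "interaction")) {
        r <- res[[part]]
        row[[paste0(part, "_beta")]] <- if (is.null(r)) NA_real_ else r$beta
        row[[paste0(part, "_p")]] <- if (is.null(r)) NA_real_ else r$p
      }
      mrows[[i]] <- row
    }
    modality <- if (length(mrows)) do.call(rbind, mrows) else NULL
  }
  if (!is.null(modality))
    utils::write.csv(modality, file.path(out_dir, "modality.csv"),
                     row.names = FALSE)
  note("modality")

  n_chr_tap <- sum(participants$group == "CHR" &
                   is.finite(participants$tap_cov_dominant %||% NA_real_))
  power_lines <- c(
    sprintf("required N to detect r = %.2f at two-sided alpha = %.2f, power = %.2f: %d",
            power_r, alpha, power_power,
            power_analysis(r = power_r, alpha = alpha, power = power_power,
                           mode = "required_n")),
    if (n_chr_tap >= 4)
      sprintf("minimal detectable r with n = %d clinical participants: %.3f",
              n_chr_tap,
              power_analysis(n = n_chr_tap, alpha = alpha, power = power_power,
                             mode = "minimal_r")))
  writeLines(power_lines, file.path(out_dir, "power.txt"))
  note("power")

  run_log <- list(mode = mode, seed = seed, alpha = alpha,
                  min_silence_s = config$min_silence_s, min_n = config$min_n,
                  log_epsilon = config$log_epsilon,
                  power_convention = list(r = power_r, power = power_power,
                                          two_sided = TRUE,
                                          fisher_z_correction = 3),
                  n_participants = nrow(participants),
                  n_samples = length(samples),
                  remote_inflation = if (mode == "simulate")
                    synth_config$remote_inflation else NA)
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("report")

  invisible(list(participants = participants, measures = measures,
                 group_results = group_results, validity = validity,
                 modality = modality, manifest = manifest))
}
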