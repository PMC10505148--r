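#' Draw positive values whose sample CoV equals a target exactly
#'
#' Draws log-normal-shaped values and rescales the log deviations (1-D root
#' finding) so that the realized sample coefficient of variation equals
#' \code{cov} exactly and the sample mean equals \code{mean}. This is how the
#' generator realizes per-participant variability targets: the participant's
#' measured CoV is their configured CoV, so cohort-level recovery of group
#' anchors is driven purely by the between-participant model.
#'
#' @param n number of values (>= 2 unless \code{cov == 0}).
#' @param mean target sample mean (> 0).
#' @param cov target sample CoV (>= 0).
#' @return numeric vector of n positive values.
#' @export
target_cov_values <- function(n, mean, cov) {
  stopifnot(mean > 0, cov >= 0, n >= 1)
  if (cov == 0 || n == 1L) {
    if (cov > 0) stop("cannot realize a positive CoV with fewer than 2 tokens",
                      call. = FALSE)
    return(rep(mean, n))
  }
  w <- stats::rnorm(n)
  w <- w - base::mean(w)
  sw <- stats::sd(w)
  if (sw < 1e-12) w <- scale(seq_len(n))[, 1] else w <- w / sw
  f <- function(a) { y <- exp(a * w); stats::sd(y) / base::mean(y) - cov }
  a <- stats::uniroot(f, c(1e-9, 5), extendInt = "upX", tol = 1e-14)$root
  y <- exp(a * w)
  y * (mean / base::mean(y))
}

# participant-level target value for a CoV-type measure: log-normal between-
# participant distribution with mean m and sd s, evaluated at deviate u
lognormal_target <- function(m, s, u) {
  if (s <= 0) return(m)
  sigma2 <- log(1 + (s / m)^2)
  exp(log(m) - sigma2 / 2 + sqrt(sigma2) * u)
}

# silences as the complement of phone intervals over [0, total]
complement_silences <- function(phones, total) {
  phones <- phones[order(phones$start_s), , drop = FALSE]
  bounds <- c(0, as.vector(rbind(phones$start_s, phones$end_s)), total)
  gs <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ge <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ge - gs > 1e-9
  if (!any(keep)) return(NULL)
  data.frame(label = "", kind = "silence", start_s = gs[keep], end_s = ge[keep],
             stringsAsFactors = FALSE)
}

sv_group_anchor <- function(config, measure, task, group, inflate = 1) {
  lk <- sv_anchor_lookup(config)
  row <- lk[paste(measure, task, sep = "."), ]
  if (group == "CHR") c(mean = row[["chr_mean"]], sd = row[["chr_sd"]] * inflate)
  else c(mean = row[["hc_mean"]], sd = row[["hc_sd"]] * inflate)
}

# group_params as a fast rowname-indexed numeric matrix
sv_anchor_lookup <- function(config) {
  gp <- config$group_params
  lk <- as.matrix(gp[, c("chr_mean", "chr_sd", "hc_mean", "hc_sd")])
  rownames(lk) <- paste(gp$measure, gp$task, sep = ".")
  lk
}

# all measure targets for one participant x task; consumes RNG in fixed order
draw_task_targets <- function(config, task, group, z, inflate,
                              anchors = sv_anchor_lookup(config)) {
  lam <- config$speech_loading
  app <- measure_applicability()
  meas <- app$measure[app$task == task]
  targets <- list()
  gcol <- if (group == "CHR") c(1L, 2L) else c(3L, 4L)
  for (m in meas) {
    a <- anchors[paste(m, task, sep = "."), gcol]
    anchor <- c(mean = a[[1]], sd = a[[2]] * inflate)
    u <- lam * z + sqrt(1 - lam^2) * stats::rnorm(1)
    targets[[m]] <- if (m %in% c("formant_dispersion_20",
                                 "formant_dispersion_change_20_50")) {
      # signed / Hz-scale measures use a normal between-participant law
      anchor[["mean"]] + anchor[["sd"]] * u
    } else if (m == "vowel_category_overlap") {
      max(0, anchor[["mean"]] + anchor[["sd"]] * u)
    } else {
      lognormal_target(anchor[["mean"]], anchor[["sd"]], u)
    }
  }
  spec <- config$task_specs[[task]]
  targets$mean_rate <- max(1.0, spec$rate_mean + spec$rate_bp_sd * stats::rnorm(1))
  targets$formant_dispersion_20 <- max(30, targets$formant_dispersion_20)
  # a phrase/trial rate CoV beyond ~1.2 is not physically realizable with
  # positive rates in a bounded recording; cap the heavy upper tail that the
  # wide spontaneous-task between-participant law occasionally produces
  if (!is.null(targets$speech_rate_cov))
    targets$speech_rate_cov <- min(targets$speech_rate_cov, 1.2)
  targets
}

#' Generate one synthetic speech sample
#'
#' Builds the segment-level realization of one participant x task given the
#' participant's measure targets: token durations realize the VOT / vowel /
#' rate CoV targets exactly (see [target_cov_values()]), formants are drawn
#' from per-category bivariate clouds whose spread follows the participant's
#' dispersion target, and silences tile the remainder of the timeline.
#' Consumes the current RNG stream; call inside a seeded substream for
#' reproducibility.
#'
#' @param participant_id id string.
#' @param task task name.
#' @param modality testing modality.
#' @param targets named list of per-measure targets as produced internally by
#'   [generate_cohort()] (components like \code{voiceless_vot_cov},
#'   \code{speech_rate_cov}, \code{mean_rate}, ...).
#' @param config an [synthetic_config()] object.
#' @return a [speech_sample()].
#' @export
generate_speech_sample <- function(participant_id, task, modality, targets,
                                   config = synthetic_config()) {
  spec <- config$task_specs[[task]]
  if (task %in% c("AMR", "SMR"))
    generate_ddk_sample(participant_id, task, modality, targets, spec, config)
  else
    generate_connected_sample(participant_id, task, modality, targets, spec, config)
}

generate_ddk_sample <- function(pid, task, modality, tg, spec, config) {
  n_tr <- spec$n_trials
  k <- spec$syll_per_trial
  # per-trial onset labels
  trial_labels <- if (task == "AMR")
    lapply(seq_len(n_tr), function(t) rep(spec$trial_onsets[t], k))
  else
    lapply(seq_len(n_tr), function(t) rep_len(spec$seq_onsets, k))
  lab_flat <- unlist(trial_labels)
  voiceless <- is_stop(lab_flat, "voiceless")

  vot <- numeric(length(lab_flat))
  n_vl <- sum(voiceless)
  if (n_vl) vot[voiceless] <- target_cov_values(n_vl, spec$vot_mean,
                                                tg$voiceless_vot_cov)
  if (any(!voiceless))
    vot[!voiceless] <- exp(stats::rnorm(sum(!voiceless),
                                        log(spec$voiced_vot_mean),
                                        spec$voiced_vot_cov * 0.8))
  vowel <- target_cov_values(length(lab_flat), spec$vowel_mean,
                             tg$vowel_duration_cov)
  gaps <- target_cov_values(n_tr * (k - 1L), spec$gap_mean,
                            tg$intersyllable_duration_cov)
  rates <- target_cov_values(n_tr, tg$mean_rate, tg$speech_rate_cov)

  sigma_f <- tg$formant_dispersion_20 / sqrt(pi / 2)
  cen <- config$formant_model$centroids[phone_base(spec$vowel_label), ]
  f1_20 <- cen[1] + stats::rnorm(length(lab_flat), 0, sigma_f)
  f2_20 <- cen[2] + stats::rnorm(length(lab_flat), 0, sigma_f)
  f1_50 <- cen[1] + spec$scale50 * (f1_20 - cen[1]) +
    stats::rnorm(length(lab_flat), 0, config$formant_model$f50_noise_sd)
  f2_50 <- cen[2] + spec$scale50 * (f2_20 - cen[2]) +
    stats::rnorm(length(lab_flat), 0, config$formant_model$f50_noise_sd)

  # per-trial duration budget: VOTs stay fixed, vowels and gaps absorb it
  trial_of <- rep(seq_len(n_tr), each = k)
  gap_trial <- rep(seq_len(n_tr), each = k - 1L)
  D <- k / rates
  fixed <- as.vector(tapply(vot, trial_of, sum))
  compress <- as.vector(tapply(vowel, trial_of, sum)) +
    as.vector(tapply(gaps, gap_trial, sum))
  f <- pmax(0.1, (D - fixed) / compress)
  vowel <- vowel * f[trial_of]
  gaps <- gaps * f[gap_trial]

  # timeline per trial: stop, vowel, gap, ..., stop, vowel; trial_gap between
  m <- 3L * k - 1L
  durs <- matrix(0, m, n_tr)
  durs[seq(1, m, by = 3), ] <- matrix(vot, k, n_tr)
  durs[seq(2, m, by = 3), ] <- matrix(vowel, k, n_tr)
  if (k > 1L) durs[seq(3, m, by = 3), ] <- matrix(gaps, k - 1L, n_tr)
  trial_dur <- colSums(durs)
  offs <- 0.5 + cumsum(c(0, trial_dur[-n_tr] + spec$trial_gap))
  ends_m <- apply(durs, 2, cumsum) + rep(offs, each = m)
  starts_m <- ends_m - durs
  tw <- cbind(offs, ends_m[m, ])
  stop_pos <- seq(1, m, by = 3)
  vow_pos <- seq(2, m, by = 3)
  sel <- as.vector(outer(c(rbind(stop_pos, vow_pos)), (seq_len(n_tr) - 1L) * m, "+"))
  is_vow_row <- rep(c(FALSE, TRUE), times = k * n_tr)
  phones <- data.frame(
    label = ifelse(is_vow_row, spec$vowel_label, rep(lab_flat, each = 2L)),
    kind = "phone",
    start_s = as.vector(starts_m)[sel],
    end_s = as.vector(ends_m)[sel],
    f1_20 = ifelse(is_vow_row, rep(f1_20, each = 2L), NA_real_),
    f2_20 = ifelse(is_vow_row, rep(f2_20, each = 2L), NA_real_),
    f1_50 = ifelse(is_vow_row, rep(f1_50, each = 2L), NA_real_),
    f2_50 = ifelse(is_vow_row, rep(f2_50, each = 2L), NA_real_),
    stringsAsFactors = FALSE)
  total <- tw[n_tr, 2] + 0.5
  trial_seg <- data.frame(label = sprintf("trial%02d", seq_len(n_tr)),
                          kind = "trial", start_s = tw[, 1], end_s = tw[, 2],
                          stringsAsFactors = FALSE)
  sil <- complement_silences(phones, total)
  segments <- rbind_fill_segments(phones, trial_seg, sil)
  speech_sample(pid, task, modality, segments,
                trial_windows = data.frame(start_s = tw[, 1], end_s = tw[, 2]),
                total_duration_s = total)
}

generate_connected_sample <- function(pid, task, modality, tg, spec, config) {
  n_ph <- spec$n_phrases
  k_p <- pmax(5L, stats::rpois(n_ph, spec$syll_per_phrase))
  n_syll <- sum(k_p)
  fm <- config$formant_model

  onset_type <- sample(c("voiceless", "voiced", "other", "none"), n_syll,
                       replace = TRUE,
                       prob = c(spec$p_voiceless, spec$p_voiced, spec$p_other,
                                1 - spec$p_voiceless - spec$p_voiced - spec$p_other))
  onset_label <- character(n_syll)
  onset_label[onset_type == "voiceless"] <-
    sample(c("P", "T", "K"), sum(onset_type == "voiceless"), replace = TRUE)
  onset_label[onset_type == "voiced"] <-
    sample(c("B", "D", "G"), sum(onset_type == "voiced"), replace = TRUE)
  onset_label[onset_type == "other"] <-
    sample(c("M", "S", "L", "N"), sum(onset_type == "other"), replace = TRUE)
  vow_cat <- sample(rownames(fm$centroids), n_syll, replace = TRUE)
  stressed <- stats::runif(n_syll) < spec$p_stress
  vow_label <- paste0(vow_cat, ifelse(stressed, "1", "0"))

  onset_dur <- numeric(n_syll)
  n_vl <- sum(onset_type == "voiceless")
  if (n_vl >= 2L)
    onset_dur[onset_type == "voiceless"] <-
      target_cov_values(n_vl, spec$vot_mean, tg$voiceless_vot_cov)
  else if (n_vl)
    onset_dur[onset_type == "voiceless"] <- spec$vot_mean
  n_vd <- sum(onset_type == "voiced")
  if (n_vd >= 2L)
    onset_dur[onset_type == "voiced"] <-
      target_cov_values(n_vd, spec$voiced_vot_mean, tg$voiced_vot_cov)
  else if (n_vd)
    onset_dur[onset_type == "voiced"] <- spec$voiced_vot_mean
  n_ot <- sum(onset_type == "other")
  if (n_ot)
    onset_dur[onset_type == "other"] <-
      exp(stats::rnorm(n_ot, log(spec$other_cons_mean), 0.3))

  vow_dur <- numeric(n_syll)
  n_st <- sum(stressed)
  if (n_st >= 2L)
    vow_dur[stressed] <- target_cov_values(n_st, spec$stressed_vowel_mean,
                                           tg$vowel_duration_cov)
  else if (n_st) vow_dur[stressed] <- spec$stressed_vowel_mean
  if (any(!stressed))
    vow_dur[!stressed] <- exp(stats::rnorm(sum(!stressed),
                                           log(spec$unstressed_vowel_mean),
                                           spec$unstressed_vowel_cov))

  subsil <- ifelse(stats::runif(n_syll) < spec$p_subsilence,
                   stats::runif(n_syll, 0.04, 0.14), 0)

  # formants: per-category clouds, spread scaled by the participant's
  # dispersion target relative to the task's default dispersion
  anchor <- sv_group_anchor(config, "formant_dispersion_20", task, "HC")
  base_sigma <- 80
  sigma_f <- base_sigma * tg$formant_dispersion_20 / anchor[["mean"]]
  cenm <- fm$centroids[vow_cat, , drop = FALSE]
  f1_20 <- cenm[, 1] + stats::rnorm(n_syll, 0, sigma_f)
  f2_20 <- cenm[, 2] + stats::rnorm(n_syll, 0, sigma_f)
  f1_50 <- cenm[, 1] + spec$scale50 * (f1_20 - cenm[, 1]) +
    stats::rnorm(n_syll, 0, fm$f50_noise_sd)
  f2_50 <- cenm[, 2] + spec$scale50 * (f2_20 - cenm[, 2]) +
    stats::rnorm(n_syll, 0, fm$f50_noise_sd)

  rates <- target_cov_values(n_ph, tg$mean_rate, tg$speech_rate_cov)
  # separating pauses always clear the 150 ms threshold
  pause_dur <- 0.151 + exp(stats::rnorm(n_ph - 1L, spec$pause_meanlog,
                                        spec$pause_sdlog))

  acc_lab <- vector("list", n_ph); acc_start <- vector("list", n_ph)
  acc_end <- vector("list", n_ph); acc_fidx <- vector("list", n_ph)
  t0 <- 0.5
  idx <- 0L
  for (p in seq_len(n_ph)) {
    ii <- idx + seq_len(k_p[p])
    D <- k_p[p] / rates[p]
    ss <- subsil[ii]
    ss[k_p[p]] <- 0                  # no trailing sub-silence inside a phrase
    # exactly-targeted tokens (VOTs, stressed vowels) and the sub-threshold
    # silences stay fixed; filler segments absorb the phrase-duration budget
    fixed <- sum(onset_dur[ii][onset_type[ii] %in% c("voiceless", "voiced")]) +
      sum(vow_dur[ii][stressed[ii]]) + sum(ss)
    compress <- sum(onset_dur[ii][onset_type[ii] == "other"]) +
      sum(vow_dur[ii][!stressed[ii]])
    f <- max(0.15, (D - fixed) / compress)
    od <- onset_dur[ii]
    od[onset_type[ii] == "other"] <- od[onset_type[ii] == "other"] * f
    vd <- vow_dur[ii]
    vd[!stressed[ii]] <- vd[!stressed[ii]] * f
    has_onset <- onset_type[ii] != "none"

    # per-syllable layout: [onset] vowel [sub-silence]
    n_per <- 1L + has_onset + (ss > 1e-9)
    m <- sum(n_per)
    labs <- character(m); durs <- numeric(m); is_phone <- logical(m)
    fidx <- integer(m)
    pos <- cumsum(c(1L, n_per[-length(n_per)]))
    for (j in seq_len(k_p[p])) {
      q <- pos[j]
      jj <- ii[j]
      if (has_onset[j]) {
        labs[q] <- onset_label[jj]; durs[q] <- od[j]; is_phone[q] <- TRUE
        q <- q + 1L
      }
      labs[q] <- vow_label[jj]; durs[q] <- vd[j]; is_phone[q] <- TRUE
      fidx[q] <- jj
      if (ss[j] > 1e-9) durs[q + 1L] <- ss[j]
    }
    ends <- t0 + cumsum(durs)
    starts <- c(t0, ends[-length(ends)])
    keep <- is_phone
    fk <- fidx[keep]
    fk[fk == 0L] <- NA_integer_      # onset consonants carry no formants
    acc_lab[[p]] <- labs[keep]
    acc_start[[p]] <- starts[keep]
    acc_end[[p]] <- ends[keep]
    acc_fidx[[p]] <- fk
    t0 <- ends[length(ends)] + if (p < n_ph) pause_dur[p] else 0
    idx <- idx + k_p[p]
  }
  fk <- unlist(acc_fidx)
  phones <- data.frame(label = unlist(acc_lab), kind = "phone",
                       start_s = unlist(acc_start), end_s = unlist(acc_end),
                       f1_20 = f1_20[fk], f2_20 = f2_20[fk],
                       f1_50 = f1_50[fk], f2_50 = f2_50[fk],
                       stringsAsFactors = FALSE)
  total <- max(phones$end_s) + 0.5
  sil <- complement_silences(phones, total)
  segments <- rbind_fill_segments(phones, NULL, sil)
  speech_sample(pid, task, modality, segments, total_duration_s = total)
}

rbind_fill_segments <- function(phones, trials, silences) {
  pad <- function(df) {
    if (is.null(df)) return(NULL)
    for (col in c("vot_s", "f1_20", "f2_20", "f1_50", "f2_50"))
      if (is.null(df[[col]])) df[[col]] <- NA_real_
    if (is.null(df$stress)) df$stress <- NA_character_
    df[, c("label", "kind", "start_s", "end_s", "vot_s",
           "f1_20", "f2_20", "f1_50", "f2_50", "stress")]
  }
  do.call(rbind, Filter(Negate(is.null), list(pad(phones), pad(trials),
                                              pad(silences))))
}

#' Generate a synthetic clinical/motor profile
#'
#' Given a participant's latent motor factor, draws finger-tapping trial
#' counts (three per hand, integer taps per 10-s trial, constructed so the
#' realized tapping CoV matches a target correlated with the factor at
#' \code{rho}), SIPS symptom totals and the motor item G3, and a conversion
#' risk score mapped monotonically into \code{risk_range}. Control
#' participants receive near-floor symptom scores and no risk score.
#' Consumes the current RNG stream.
#'
#' @param group \code{"CHR"} or \code{"HC"}.
#' @param z latent motor factor (standard normal scale).
#' @param config an [synthetic_config()].
#' @return named list of profile fields.
#' @export
.sv_tap_bits <- as.matrix(expand.grid(b1 = -1:1, b2 = -1:1, b3 = -1:1))

generate_clinical_profile <- function(group, z, config = synthetic_config()) {
  rho <- config$rho
  tp <- config$tapping
  mix <- function() rho * z + sqrt(1 - rho^2) * stats::rnorm(1)

  tap_hand <- function(count_mean, cov_mean, cov_sd) {
    v <- mix()
    target <- max(tp$min_cov, cov_mean + cov_sd * v)
    m <- max(20, round(count_mean + tp$count_sd * stats::rnorm(1)))
    d <- target * m
    base <- c(m - d, m, m + d)
    # choose the integer rounding that best matches the target CoV
    grid <- round(base)[col(.sv_tap_bits)] + .sv_tap_bits
    mu <- rowMeans(grid)
    sds <- sqrt((rowSums(grid^2) - 3 * mu^2) / 2)
    counts <- grid[which.min(abs(sds / mu - target)), ]
    pmax(counts, 1L)
  }
  tap_dom <- tap_hand(tp$dom_count_mean, tp$dom_cov_mean, tp$dom_cov_sd)
  tap_nd <- tap_hand(tp$nd_count_mean, tp$nd_cov_mean, tp$nd_cov_sd)

  sp <- config$sips
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  if (group == "CHR") {
    pos <- clamp(round(sp$pos_mean + sp$pos_sd * mix()), 0, 30)
    neg <- clamp(round(sp$neg_mean + sp$neg_sd * mix()), 0, 36)
    dis <- clamp(round(sp$dis_mean + sp$dis_sd * mix()), 0, 24)
    g3 <- clamp(round(sp$g3_mean + sp$g3_sd * mix()), 0, 6)
    rr <- config$risk_range
    risk <- rr[1] + (rr[2] - rr[1]) * stats::pnorm(mix())
  } else {
    pos <- sample(0:2, 1)
    neg <- sample(0:2, 1)
    dis <- sample(0:1, 1)
    g3 <- 0L
    risk <- NA_real_
  }
  list(tap_dom = tap_dom, tap_nd = tap_nd,
       sips_positive_total = pos, sips_negative_total = neg,
       sips_disorganized_total = dis, sips_g3 = g3, sips_rc_risk = risk)
}

draw_demographics <- function(group) {
  if (group == "CHR") {
    age <- max(16, 21.8 + 2.8 * stats::rnorm(1))
    sex <- if (stats::runif(1) < 0.607) "F" else "M"
    race <- sample(c("White", "Black", "Asian", "CentralSouthAmerican",
                     "PacificIslander", "Multiracial"), 1,
                   prob = c(0.446, 0.196, 0.179, 0.089, 0.018, 0.072))
    eth <- if (stats::runif(1) < 0.268) "Hispanic" else "NotHispanic"
    lang <- sample(c("English", "Other", "NotReported"), 1,
                   prob = c(0.625, 0.179, 0.196))
  } else {
    age <- max(16, 21.7 + 3.2 * stats::rnorm(1))
    sex <- if (stats::runif(1) < 0.621) "F" else "M"
    race <- sample(c("White", "Black", "Asian", "FirstNations", "Multiracial"),
                   1, prob = c(0.455, 0.091, 0.288, 0.030, 0.136))
    eth <- if (stats::runif(1) < 0.106) "Hispanic" else "NotHispanic"
    lang <- sample(c("English", "Other", "NotReported"), 1,
                   prob = c(0.803, 0.182, 0.015))
  }
  list(age = age, sex = sex, race = race, ethnicity = eth, first_language = lang)
}

#' Generate a full synthetic cohort
#'
#' Deterministically generates a two-group cohort from \code{(config, seed)}:
#' each participant draws from an independent seeded substream, so removing a
#' participant leaves every other participant's data unchanged, and repeated
#' calls are identical. Per participant the generator draws a latent motor
#' factor, modality, demographics, a clinical/motor profile (see
#' [generate_clinical_profile()]) and per-task measure targets; with
#' \code{detail = "segments"} it additionally materializes segment-level
#' speech samples realizing those targets (see [generate_speech_sample()]).
#' With \code{detail = "measures"} the measure table is emitted directly from
#' the targets — identical (for the exactly-realized CoV and rate measures)
#' to computing the battery on generated segments, but much faster for
#' Monte-Carlo studies.
#'
#' @param config an [synthetic_config()].
#' @param seed integer master seed.
#' @param detail \code{"segments"} (full samples plus measure table computed
#'   from them on demand) or \code{"measures"} (measure table only).
#' @return list with \code{participants} (data frame), \code{samples} (named
#'   list of [speech_sample()], segments detail only), \code{measures} (a
#'   \code{measure_table}, measures detail only), and \code{config}.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1L,
                            detail = c("segments", "measures")) {
  detail <- match.arg(detail)
  tasks <- config$tasks
  n_chr_pool <- max(config$n_chr[tasks])
  n_hc_pool <- max(config$n_hc[tasks])
  ids <- c(sprintf("CHR%03d", seq_len(n_chr_pool)),
           sprintf("HC%03d", seq_len(n_hc_pool)))
  groups <- c(rep("CHR", n_chr_pool), rep("HC", n_hc_pool))
  g_index <- c(seq_len(n_chr_pool), seq_len(n_hc_pool))

  part_rows <- vector("list", length(ids))
  samples <- list()
  measure_rows <- list()
  anchors <- sv_anchor_lookup(config)

  for (i in seq_along(ids)) {
    # key the substream on (group, within-group index) so resizing one
    # group's pool never perturbs the other group's participants
    sub_seed <- participant_seed(seed, g_index[i] +
                                   if (groups[i] == "HC") 100000L else 0L)
    set.seed(sub_seed)
    group <- groups[i]
    z <- stats::rnorm(1)
    p_in <- if (group == "CHR") config$modality_split[["chr_in_person"]]
            else config$modality_split[["hc_in_person"]]
    modality <- if (stats::runif(1) < p_in) "in_person" else "remote"
    dem <- draw_demographics(group)
    prof <- generate_clinical_profile(group, z, config)
    inflate <- if (group == "HC" && modality == "remote")
      config$remote_inflation else 1

    my_tasks <- tasks[vapply(tasks, function(t) {
      n <- if (group == "CHR") config$n_chr[[t]] else config$n_hc[[t]]
      g_index[i] <= n
    }, logical(1))]

    targets <- lapply(my_tasks, function(t)
      draw_task_targets(config, t, group, z, inflate, anchors))
    names(targets) <- my_tasks

    if (detail == "segments") {
      for (t in my_tasks) {
        s <- generate_speech_sample(ids[i], t, modality, targets[[t]], config)
        samples[[paste(ids[i], t, sep = ".")]] <- s
      }
    } else {
      for (t in my_tasks)
        measure_rows[[length(measure_rows) + 1L]] <-
          targets_to_measure_rows(ids[i], t, modality, targets[[t]])
    }

    part_rows[[i]] <- list(
      participant_id = ids[i], group = group, modality = modality,
      age = dem$age, sex = dem$sex, race = dem$race,
      ethnicity = dem$ethnicity, first_language = dem$first_language,
      sips_positive_total = prof$sips_positive_total,
      sips_negative_total = prof$sips_negative_total,
      sips_disorganized_total = prof$sips_disorganized_total,
      sips_g3 = prof$sips_g3,
      tap_dom_1 = prof$tap_dom[1], tap_dom_2 = prof$tap_dom[2],
      tap_dom_3 = prof$tap_dom[3],
      tap_nd_1 = prof$tap_nd[1], tap_nd_2 = prof$tap_nd[2],
      tap_nd_3 = prof$tap_nd[3],
      tap_cov_dominant = as.numeric(finger_tapping_cov(prof$tap_dom)),
      tap_cov_nondominant = as.numeric(finger_tapping_cov(prof$tap_nd)),
      sips_rc_risk = prof$sips_rc_risk,
      latent_motor = z)
  }

  cols <- names(part_rows[[1]])
  participants <- as.data.frame(
    lapply(stats::setNames(cols, cols), function(cn)
      unlist(lapply(part_rows, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE)
  out <- list(participants = participants, config = config, seed = seed)
  if (detail == "segments") {
    out$samples <- samples
  } else {
    tab <- data.frame(
      participant_id = unlist(lapply(measure_rows, `[[`, "participant_id")),
      task = unlist(lapply(measure_rows, `[[`, "task")),
      modality = unlist(lapply(measure_rows, `[[`, "modality")),
      measure = unlist(lapply(measure_rows, `[[`, "measure")),
      raw = unlist(lapply(measure_rows, `[[`, "raw")),
      log = NA_real_,
      n_tokens = unlist(lapply(measure_rows, `[[`, "n_tokens")),
      missing_reason = NA_character_,
      mean_rate = unlist(lapply(measure_rows, `[[`, "mean_rate")),
      stringsAsFactors = FALSE)
    class(tab) <- c("measure_table", "data.frame")
    out$measures <- log_transform_measures(tab)
  }
  out
}

participant_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 1000003 + index * 7919) %% 2147483647
  as.integer(max(1, s))
}

# nominal token counts behind each measure, for the measures-only detail
.sv_nominal_tokens <- c(voiceless_vot_cov = 90L, voiced_vot_cov = 25L,
                        speech_rate_cov = 12L, vowel_duration_cov = 150L,
                        formant_dispersion_20 = 150L,
                        formant_dispersion_change_20_50 = 150L,
                        vowel_category_overlap = 150L,
                        syllable_duration_cov = 180L,
                        intersyllable_duration_cov = 168L,
                        pause_rate = NA_integer_)

targets_to_measure_rows <- function(pid, task, modality, tg) {
  app <- measure_applicability()
  meas <- app$measure[app$task == task]
  list(participant_id = rep(pid, length(meas)),
       task = rep(task, length(meas)),
       modality = rep(modality, length(meas)),
       measure = meas,
       raw = vapply(meas, function(m) tg[[m]], numeric(1), USE.NAMES = FALSE),
       n_tokens = unname(.sv_nominal_tokens[meas]),
       mean_rate = rep(tg$mean_rate, length(meas)))
}
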