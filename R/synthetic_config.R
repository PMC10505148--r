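#' Default group-level anchors for the measure battery
#'
#' Per measure x task, the target mean and between-participant SD of each
#' group's measure distribution. These defaults encode the variability
#' profile of a clinical-high-risk cohort versus healthy controls: elevated
#' voiceless-VOT CoV and speech-rate CoV in the DDK and read tasks, a null
#' spontaneous-task contrast, and matched vowel/pause measures.
#'
#' @return data frame with columns \code{measure, task, chr_mean, chr_sd,
#'   hc_mean, hc_sd}.
#' @export
default_group_params <- function() {
  p <- rbind(
    c("voiceless_vot_cov", "AMR",   0.31, 0.09, 0.27, 0.10),
    c("voiceless_vot_cov", "SMR",   0.39, 0.10, 0.35, 0.09),
    c("voiceless_vot_cov", "READ",  0.43, 0.10, 0.39, 0.07),
    c("voiceless_vot_cov", "SPONT", 0.40, 0.09, 0.40, 0.07),
    c("voiced_vot_cov",    "READ",  0.70, 0.26, 0.71, 0.26),
    c("voiced_vot_cov",    "SPONT", 0.66, 0.26, 0.58, 0.31),
    c("speech_rate_cov",   "AMR",   0.07, 0.04, 0.05, 0.04),
    c("speech_rate_cov",   "SMR",   0.10, 0.05, 0.08, 0.04),
    c("speech_rate_cov",   "READ",  0.20, 0.05, 0.18, 0.06),
    c("speech_rate_cov",   "SPONT", 0.43, 0.45, 0.37, 0.32),
    c("vowel_duration_cov", "AMR",   0.20, 0.09, 0.17, 0.09),
    c("vowel_duration_cov", "SMR",   0.43, 0.12, 0.40, 0.15),
    c("vowel_duration_cov", "READ",  0.56, 0.05, 0.56, 0.06),
    c("vowel_duration_cov", "SPONT", 0.74, 0.11, 0.73, 0.09),
    c("formant_dispersion_20", "AMR",   158.63, 86.40, 128.85, 64.57),
    c("formant_dispersion_20", "SMR",   211.70, 85.72, 185.02, 75.80),
    c("formant_dispersion_20", "READ",  341.76, 53.41, 332.50, 48.44),
    c("formant_dispersion_20", "SPONT", 357.52, 48.52, 362.32, 58.29),
    c("formant_dispersion_change_20_50", "AMR",   14.59, 21.02, 10.68, 20.01),
    c("formant_dispersion_change_20_50", "SMR",   20.33, 20.06, 19.41, 19.17),
    c("formant_dispersion_change_20_50", "READ", -22.07, 14.82, -21.99, 15.20),
    c("formant_dispersion_change_20_50", "SPONT", -4.50, 16.36, -2.06, 17.79),
    c("vowel_category_overlap", "READ",  0.8, 5.91, 0.0, 0.0),
    c("vowel_category_overlap", "SPONT", 0.0, 0.0, 0.0, 0.0),
    c("syllable_duration_cov", "AMR", 0.21, 0.09, 0.17, 0.08),
    c("syllable_duration_cov", "SMR", 0.39, 0.10, 0.36, 0.13),
    c("intersyllable_duration_cov", "AMR", 0.42, 0.25, 0.34, 0.18),
    c("intersyllable_duration_cov", "SMR", 0.90, 0.27, 0.82, 0.23),
    c("pause_rate", "READ",  0.10, 0.03, 0.09, 0.03),
    c("pause_rate", "SPONT", 0.15, 0.05, 0.14, 0.07))
  out <- data.frame(measure = p[, 1], task = p[, 2],
                    chr_mean = as.numeric(p[, 3]), chr_sd = as.numeric(p[, 4]),
                    hc_mean = as.numeric(p[, 5]), hc_sd = as.numeric(p[, 6]),
                    stringsAsFactors = FALSE)
  out
}

#' Group anchors with the clinical effect removed
#'
#' Convenience for null simulations (e.g. type-I calibration): both groups
#' get the control group's mean and SD.
#'
#' @param params a [default_group_params()]-shaped data frame.
#' @export
null_group_params <- function(params = default_group_params()) {
  params$chr_mean <- params$hc_mean
  params$chr_sd <- params$hc_sd
  params
}

#' Per-task structural specifications of the synthetic tasks
#'
#' Emulated structure: AMR = 12 trials of one CV syllable repeated 15 times
#' (two trials per place for p/t/k/b/d/g); SMR = 20 trials of a three-syllable
#' voiceless sequence repeated 10 times (30 syllables per trial); READ = a
#' phonetically-dense read passage emulated as ~9 phrases of ~37 syllables;
#' SPONT = a ~2-minute spontaneous sample of ~19 phrases. Durations are in
#' seconds, rates in syllables per second; \code{scale50} is the factor by
#' which the 50\%-timepoint formant cloud is scaled about the category
#' centroid relative to the 20\% cloud.
#'
#' @return named list of per-task spec lists.
#' @export
default_task_specs <- function() {
  list(
    AMR = list(n_trials = 12L, syll_per_trial = 15L,
               trial_onsets = rep(c("P", "T", "K", "B", "D", "G"), each = 2L),
               rate_mean = 5.0, rate_bp_sd = 0.4,
               vot_mean = 0.060, voiced_vot_mean = 0.018, voiced_vot_cov = 0.5,
               vowel_mean = 0.100, gap_mean = 0.045, trial_gap = 1.0,
               vowel_label = "AA1", scale50 = 1.092),
    SMR = list(n_trials = 20L, syll_per_trial = 30L,
               seq_onsets = c("P", "T", "K"),
               rate_mean = 6.0, rate_bp_sd = 0.5,
               vot_mean = 0.050, vowel_mean = 0.070, gap_mean = 0.030,
               trial_gap = 1.0, vowel_label = "AA1", scale50 = 1.096),
    READ = list(n_phrases = 9L, syll_per_phrase = 37L,
                rate_mean = 4.5, rate_bp_sd = 0.35,
                p_voiceless = 0.12, p_voiced = 0.08, p_other = 0.45,
                p_stress = 0.45, p_subsilence = 0.10,
                vot_mean = 0.070, voiced_vot_mean = 0.022,
                stressed_vowel_mean = 0.120, unstressed_vowel_mean = 0.080,
                unstressed_vowel_cov = 0.40, other_cons_mean = 0.070,
                pause_meanlog = log(0.25), pause_sdlog = 0.5,
                scale50 = 0.935),
    SPONT = list(n_phrases = 19L, syll_per_phrase = 23L,
                 rate_mean = 4.0, rate_bp_sd = 0.35,
                 p_voiceless = 0.10, p_voiced = 0.07, p_other = 0.48,
                 p_stress = 0.45, p_subsilence = 0.12,
                 vot_mean = 0.070, voiced_vot_mean = 0.022,
                 stressed_vowel_mean = 0.130, unstressed_vowel_mean = 0.085,
                 unstressed_vowel_cov = 0.40, other_cons_mean = 0.070,
                 pause_meanlog = log(0.28), pause_sdlog = 0.5,
                 scale50 = 0.987))
}

# vowel category centroids (F1, F2) in Hz for the synthetic formant clouds
default_formant_model <- function() {
  list(centroids = rbind(AA = c(850, 1450), IY = c(300, 2700),
                         UW = c(350, 900), EH = c(600, 1900),
                         OW = c(500, 1000)),
       f50_noise_sd = 5)
}

#' Full configuration of the synthetic cohort generator
#'
#' The generator emulates a two-group (CHR vs HC) speech study: per-task
#' sample sizes default to a DDK subsample of 51/53, a read subsample of
#' 55/65, and a spontaneous subsample of 50/50 drawn from pools of 55 CHR and
#' 65 HC participants. A per-participant latent motor factor links speech
#' variability to the motor/clinical covariates: each speech measure's
#' participant-level deviate loads on the factor with \code{speech_loading},
#' and the tapping/symptom/risk deviates correlate with the factor at
#' \code{rho}, so the implied speech-tapping correlation is
#' \code{speech_loading * rho}.
#'
#' @param n_chr,n_hc named integer vectors of per-task group sizes.
#' @param tasks tasks to generate.
#' @param group_params measure anchors, see [default_group_params()].
#' @param task_specs see [default_task_specs()].
#' @param speech_loading loading of each speech measure's deviate on the
#'   latent factor, in [0, 1].
#' @param rho correlation of the tapping/SIPS/risk deviates with the latent
#'   factor, in (-1, 1).
#' @param tapping,sips parameter lists for the motor and clinical covariates.
#' @param risk_range range of the conversion-risk score (percent).
#' @param modality_split probability of in-person testing per group.
#' @param remote_inflation multiplier on the between-participant SD of every
#'   measure for remotely-tested control participants (1 = off).
#' @return list of class \code{sv_synth_config}.
#' @export
synthetic_config <- function(n_chr = c(AMR = 51L, SMR = 51L, READ = 55L, SPONT = 50L),
                             n_hc = c(AMR = 53L, SMR = 53L, READ = 65L, SPONT = 50L),
                             tasks = c("AMR", "SMR", "READ", "SPONT"),
                             group_params = default_group_params(),
                             task_specs = default_task_specs(),
                             speech_loading = 0.6,
                             rho = 0.37,
                             tapping = list(dom_count_mean = 62, nd_count_mean = 55,
                                            count_sd = 6,
                                            dom_cov_mean = 0.05, dom_cov_sd = 0.025,
                                            nd_cov_mean = 0.06, nd_cov_sd = 0.03,
                                            min_cov = 0.002),
                             sips = list(pos_mean = 11, pos_sd = 4,
                                         neg_mean = 10, neg_sd = 5,
                                         dis_mean = 4, dis_sd = 2,
                                         g3_mean = 1, g3_sd = 1),
                             risk_range = c(0.8, 10.1),
                             modality_split = c(chr_in_person = 26 / 56,
                                                hc_in_person = 44 / 66),
                             remote_inflation = 1) {
  tasks <- match.arg(tasks, c("AMR", "SMR", "READ", "SPONT"), several.ok = TRUE)
  if (abs(rho) >= 1) stop("rho must be inside (-1, 1)", call. = FALSE)
  if (speech_loading < 0 || speech_loading > 1)
    stop("speech_loading must be in [0, 1]", call. = FALSE)
  if (any(group_params$chr_sd < 0) || any(group_params$hc_sd < 0))
    stop("group SDs must be non-negative", call. = FALSE)
  if (any(n_chr[tasks] <= 0) || any(n_hc[tasks] <= 0))
    stop("group sizes must be positive", call. = FALSE)
  structure(list(n_chr = n_chr, n_hc = n_hc, tasks = tasks,
                 group_params = group_params, task_specs = task_specs,
                 formant_model = default_formant_model(),
                 speech_loading = speech_loading, rho = rho,
                 tapping = tapping, sips = sips, risk_range = risk_range,
                 modality_split = modality_split,
                 remote_inflation = remote_inflation),
            class = "sv_synth_config")
}
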