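#' Two-group comparison of one speech measure
#'
#' Ordinary least squares of the log-transformed measure on a group indicator
#' (clinical group = 1, control = 0). For durational measures (the
#' CoV-of-duration family, see [measure_applicability()]) the participant's
#' averaged speech rate for the task enters as an additional predictor, so
#' that duration-variability effects are not driven by overall speaking rate.
#' Participants missing the measure or a covariate are dropped listwise.
#'
#' @param table a \code{measure_table} (see [compute_measure_table()]).
#' @param participants participant data frame with columns
#'   \code{participant_id}, \code{group} (\code{"CHR"}/\code{"HC"}) and
#'   \code{modality}.
#' @param measure measure name (see [measure_applicability()]).
#' @param task task name.
#' @param adjust_rate force the rate covariate on/off; default follows the
#'   measure's durational flag.
#' @return object of class \code{sv_regression}: list with \code{beta},
#'   \code{se}, \code{t}, \code{p} (two-sided) for the group term, \code{n},
#'   and \code{covariates}.
#' @export
fit_group_difference <- function(table, participants, measure, task,
                                 adjust_rate = NULL) {
  d <- measure_frame(table, participants, measure, task)
  if (is.null(adjust_rate)) {
    app <- measure_applicability()
    adjust_rate <- app$durational[match(measure, app$measure)]
  }
  covariates <- character(0)
  if (isTRUE(adjust_rate)) {
    d <- d[is.finite(d$mean_rate), , drop = FALSE]
    if (nrow(d) && stats::var(d$mean_rate) > 0) covariates <- "mean_rate"
    else if (nrow(d)) warning("constant speech-rate covariate dropped", call. = FALSE)
  }
  for (g in c("CHR", "HC"))
    if (sum(d$group == g) < 3L)
      stop("fewer than 3 ", g, " participants with measure ", measure,
           " in task ", task, call. = FALSE)
  d$group_chr <- as.numeric(d$group == "CHR")
  fml <- if (length(covariates)) log ~ group_chr + mean_rate else log ~ group_chr
  fit <- stats::lm(fml, data = d)
  sv_regression(fit, "group_chr", n = nrow(d), covariates = covariates,
                measure = measure, task = task)
}

measure_frame <- function(table, participants, measure, task) {
  d <- table[table$measure == measure & table$task == task, , drop = FALSE]
  d <- d[!is.na(d$log), , drop = FALSE]
  idx <- match(d$participant_id, participants$participant_id)
  d$group <- participants$group[idx]
  d[!is.na(d$group), , drop = FALSE]
}

sv_regression <- function(fit, term, n, covariates, ...) {
  cf <- summary(fit)$coefficients
  if (!term %in% rownames(cf))
    stop("term ", term, " not estimable", call. = FALSE)
  structure(list(beta = unname(cf[term, 1]), se = unname(cf[term, 2]),
                 t = unname(cf[term, 3]), p = unname(cf[term, 4]),
                 n = n, covariates = covariates, term = term, ...),
            class = "sv_regression")
}

#' @export
print.sv_regression <- function(x, ...) {
  cat(sprintf("beta = %.4g, s.e. = %.4g, t = %.3g, p = %.3g (n = %d%s)\n",
              x$beta, x$se, x$t, x$p, x$n,
              if (length(x$covariates))
                paste0("; adjusted for ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Validity correlation of a speech measure within the clinical group
#'
#' Pearson correlation (with two-sided p) between the log measure and a
#' clinical/motor/risk validation field, computed within the clinical (CHR)
#' group only, as in a convergent-validity analysis. Pairs with a missing
#' value on either side are dropped.
#'
#' @inheritParams fit_group_difference
#' @param validation_field name of a numeric column of \code{participants}
#'   (e.g. \code{sips_negative_total}, \code{tap_cov_dominant},
#'   \code{sips_rc_risk}).
#' @return list of class \code{sv_correlation} with \code{r}, \code{p},
#'   \code{n}.
#' @export
fit_validity_correlation <- function(table, participants, measure, task,
                                     validation_field) {
  d <- measure_frame(table, participants, measure, task)
  d <- d[d$group == "CHR", , drop = FALSE]
  idx <- match(d$participant_id, participants$participant_id)
  v <- participants[[validation_field]][idx]
  ok <- is.finite(d$log) & is.finite(v)
  x <- d$log[ok]; y <- v[ok]
  if (length(x) < 4L)
    stop("fewer than 4 complete pairs for ", measure, " vs ",
         validation_field, call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::var(x) == 0) measure else validation_field, call. = FALSE)
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 measure = measure, task = task,
                 validation_field = validation_field),
            class = "sv_correlation")
}

#' @export
print.sv_correlation <- function(x, ...) {
  cat(sprintf("r = %.3g (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Coefficient of variation of finger-tapping counts
#'
#' Sample SD / mean of the number of taps across the first three trials of
#' one hand (taps per 10-second trial). Extra trials beyond the first three
#' are ignored; with fewer than three the value is missing.
#'
#' @param counts numeric vector of per-trial tap counts.
#' @return CoV, or \code{NA} with \code{missing_reason} attribute.
#' @export
finger_tapping_cov <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < 3L)
    return(structure(NA_real_, missing_reason = "fewer_than_3_trials"))
  coefficient_of_variation(counts[1:3], min_n = 2L)
}

#' Modality-stratified group comparison
#'
#' Refits the group comparison separately for in-person and remote
#' participants and, in addition, fits a full-sample model with a group x
#' modality interaction. A modality whose group cell is empty is skipped with
#' a warning; the interaction model requires both modalities.
#'
#' @inheritParams fit_group_difference
#' @return list with components \code{in_person}, \code{remote} (each an
#'   \code{sv_regression} or \code{NULL}) and \code{interaction}.
#' @export
modality_stratified_analysis <- function(table, participants, measure, task,
                                         adjust_rate = NULL) {
  strata <- list(in_person = NULL, remote = NULL)
  for (m in c("in_person", "remote")) {
    keep <- participants[participants$modality == m, , drop = FALSE]
    res <- try(fit_group_difference(table, keep, measure, task, adjust_rate),
               silent = TRUE)
    if (inherits(res, "try-error"))
      warning("stratum ", m, " skipped: insufficient data", call. = FALSE)
    else strata[[m]] <- res
  }
  interaction <- NULL
  if (!is.null(strata$in_person) && !is.null(strata$remote)) {
    d <- measure_frame(table, participants, measure, task)
    idx <- match(d$participant_id, participants$participant_id)
    d$modality_remote <- as.numeric(participants$modality[idx] == "remote")
    d$group_chr <- as.numeric(d$group == "CHR")
    if (is.null(adjust_rate)) {
      app <- measure_applicability()
      adjust_rate <- app$durational[match(measure, app$measure)]
    }
    if (isTRUE(adjust_rate)) d <- d[is.finite(d$mean_rate), , drop = FALSE]
    fml <- if (isTRUE(adjust_rate))
      log ~ group_chr * modality_remote + mean_rate
    else log ~ group_chr * modality_remote
    fit <- stats::lm(fml, data = d)
    interaction <- sv_regression(fit, "group_chr:modality_remote", n = nrow(d),
                                 covariates = if (isTRUE(adjust_rate)) "mean_rate"
                                 else character(0),
                                 measure = measure, task = task)
  }
  list(in_person = strata$in_person, remote = strata$remote,
       interaction = interaction)
}

#' Demographic-confound regressions and leave-one-out classification
#'
#' For each demographic factor, fits a regression predicting the factor from
#' the (log) speech measure: OLS for continuous factors (age), logistic for
#' categorical ones (sex, race, first language; multi-level factors are
#' binarized as most-frequent level vs. rest). Constant factors are skipped.
#' Also reports the leave-one-out accuracy of a univariate logistic
#' classifier of group membership from the measure.
#'
#' @inheritParams fit_group_difference
#' @param demographics character vector of participant columns to test.
#' @return list with \code{confounds} (named list of \code{sv_regression})
#'   and \code{loo_accuracy} (proportion in [0, 1]).
#' @export
confound_and_classification <- function(table, participants, measure, task,
                                        demographics = c("age", "sex", "race",
                                                         "first_language")) {
  d <- measure_frame(table, participants, measure, task)
  idx <- match(d$participant_id, participants$participant_id)

  confounds <- list()
  for (dem in demographics) {
    y <- participants[[dem]][idx]
    if (is.null(y)) next
    if (is.numeric(y)) {
      ok <- is.finite(y) & is.finite(d$log)
      if (sum(ok) < 4L || stats::var(y[ok]) == 0) next
      fit <- stats::lm(y[ok] ~ d$log[ok])
      confounds[[dem]] <- sv_regression(fit, "d$log[ok]", n = sum(ok),
                                        covariates = character(0),
                                        demographic = dem)
    } else {
      y <- as.character(y)
      ok <- !is.na(y) & nzchar(y) & is.finite(d$log)
      if (sum(ok) < 4L) next
      tab <- base::table(y[ok])
      if (length(tab) < 2L) next  # constant factor
      top <- names(tab)[which.max(tab)]
      yy <- as.numeric(y[ok] == top)
      fit <- stats::glm(yy ~ d$log[ok], family = stats::binomial())
      cf <- summary(fit)$coefficients
      confounds[[dem]] <- structure(
        list(beta = unname(cf[2, 1]), se = unname(cf[2, 2]),
             t = unname(cf[2, 3]), p = unname(cf[2, 4]), n = sum(ok),
             covariates = character(0), demographic = dem,
             contrast = paste0(top, " vs rest")),
        class = "sv_regression")
    }
  }

  ok <- is.finite(d$log) & d$group %in% c("CHR", "HC")
  x <- d$log[ok]; g <- as.numeric(d$group[ok] == "CHR")
  loo <- NA_real_
  if (length(x) >= 4L && stats::var(x) > 0 && length(unique(g)) == 2L) {
    pred <- vapply(seq_along(x), function(i) {
      fit <- suppressWarnings(
        stats::glm(g[-i] ~ x[-i], family = stats::binomial()))
      eta <- stats::coef(fit)[1] + stats::coef(fit)[2] * x[i]
      as.numeric(eta > 0)
    }, numeric(1))
    loo <- mean(pred == g)
  }
  list(confounds = confounds, loo_accuracy = loo)
}

#' Fisher-z power analytics for a Pearson correlation
#'
#' Two-sided test of a correlation via the Fisher z transform with the usual
#' small-sample correction (variance \eqn{1/(n-3)}):
#' \deqn{n_{req} = \lceil ((z_{1-\alpha/2} + z_{power}) / \mathrm{atanh}(r))^2 + 3 \rceil}
#' \deqn{r_{min} = \tanh((z_{1-\alpha/2} + z_{power}) / \sqrt{n-3})}
#'
#' @param r target correlation (mode \code{"required_n"}).
#' @param n available sample size (mode \code{"minimal_r"}).
#' @param alpha two-sided type-I level.
#' @param power desired power (1 - type-II rate).
#' @param mode \code{"required_n"} or \code{"minimal_r"}.
#' @return required sample size (integer) or minimal detectable correlation.
#' @examples
#' power_analysis(r = 0.37, mode = "required_n")   # 56
#' power_analysis(n = 50, mode = "minimal_r")      # ~0.387
#' @export
power_analysis <- function(r = NULL, n = NULL, alpha = 0.05, power = 0.80,
                           mode = c("required_n", "minimal_r")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  zcrit <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  if (mode == "required_n") {
    if (is.null(r)) stop("mode 'required_n' needs r", call. = FALSE)
    if (r == 0) stop("required n diverges at r = 0", call. = FALSE)
    as.integer(ceiling((zcrit / atanh(abs(r)))^2 + 3))
  } else {
    if (is.null(n)) stop("mode 'minimal_r' needs n", call. = FALSE)
    if (n < 4) stop("minimal_r needs n >= 4", call. = FALSE)
    tanh(zcrit / sqrt(n - 3))
  }
}
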