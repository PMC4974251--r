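CUES <- c("directional", "non-directional")
HANDS <- c("left", "right")

cue_cells <- function() {
  paste(rep(CUES, each = 2), rep(HANDS, 2), sep = ".")
}

named_by_cue <- function(x) {
  if (length(x) == 1) x <- rep(x, 2)
  stats::setNames(as.numeric(x), CUES)
}

named_by_cell <- function(x) {
  if (length(x) == 1) x <- rep(x, 4)
  if (length(x) == 2) x <- rep(x, each = 2)  # per-cue value for both hands
  stats::setNames(as.numeric(x), cue_cells())
}

#' Ground-truth component parameters of one simulated participant
#'
#' Holds the per-condition generator settings whose window-aggregated values
#' the measurement pipeline is built to recover: CNV mean amplitude (uV,
#' negative, per cue condition), P300 peak amplitude (uV) and latency
#' (ms post-target), lateralized motor-potential amplitude (uV, negative,
#' contralateral minus ipsilateral), target-locked and response-locked LRP
#' onsets (25% fractional-area latency, ms, per cue condition), ex-Gaussian
#' response-time parameters per cue x hand cell, omission and false-alarm
#' rates, and the noise model (1/f^alpha RMS, 50 Hz line amplitude).
#'
#' `stim_effect` is an additive shift applied under active stimulation to
#' `rt_mu`, `cnv_amp`, `tlrp_onset` and `rlrp_onset`; its default of zero
#' makes the two stimulation sessions exchangeable, i.e. a true null.
#'
#' Defaults are the young-adult condition means (see
#' [experiment_profile()] for both profiles). Dispersion parameters
#' (`rt_sigma`, `rt_tau`, `noise_rms`) are conventions documented in the
#' methods vignette; the source study reports only cell means.
#'
#' @param cnv_amp CNV mean amplitude per cue condition, uV (<= 0).
#' @param cnv_onset CNV onset, ms post-cue.
#' @param p300_amp P300 peak amplitude per cue condition, uV.
#' @param p300_lat P300 peak latency per cue condition, ms post-target.
#' @param p300_width Gaussian width (sd) of the P300 template, ms.
#' @param lrp_amp lateralized motor amplitude, uV (<= 0).
#' @param tlrp_onset target-locked LRP onset per cue condition, ms.
#' @param rlrp_onset response-locked LRP onset per cue condition, ms (< 0).
#' @param rt_mu,rt_sigma,rt_tau ex-Gaussian RT parameters per cue x hand
#'   cell, ms (recycled from length 1, 2 = per cue, or 4).
#' @param miss_rate omission probability on go trials.
#' @param false_alarm_rate response probability on nogo trials.
#' @param noise_rms background-noise RMS per channel, uV.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha noise.
#' @param line_amp 50 Hz line-noise amplitude, uV.
#' @param stim_effect named list of additive shifts under active stimulation
#'   (`rt_mu`, `cnv_amp`, `tlrp_onset`, `rlrp_onset`).
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(cnv_amp = c(-4.9, -2.8), cnv_onset = 500,
                           p300_amp = c(10.9, 16.2), p300_lat = c(335, 345),
                           p300_width = 50,
                           lrp_amp = -3.5,
                           tlrp_onset = c(271, 313),
                           rlrp_onset = c(-109, -131),
                           rt_mu = c(334, 328, 412, 389),
                           rt_sigma = 40, rt_tau = 60,
                           miss_rate = 0.0161, false_alarm_rate = 0.001,
                           noise_rms = 4, noise_exponent = 1, line_amp = 2,
                           stim_effect = list()) {
  p <- list(
    cnv_amp = named_by_cue(cnv_amp), cnv_onset = cnv_onset,
    p300_amp = named_by_cue(p300_amp), p300_lat = named_by_cue(p300_lat),
    p300_width = p300_width,
    lrp_amp = as.numeric(lrp_amp),
    tlrp_onset = named_by_cue(tlrp_onset),
    rlrp_onset = named_by_cue(rlrp_onset),
    rt_mu = named_by_cell(rt_mu),
    rt_sigma = named_by_cell(rt_sigma), rt_tau = named_by_cell(rt_tau),
    miss_rate = miss_rate, false_alarm_rate = false_alarm_rate,
    noise_rms = noise_rms, noise_exponent = noise_exponent,
    line_amp = line_amp,
    stim_effect = utils::modifyList(
      list(rt_mu = 0, cnv_amp = 0, tlrp_onset = 0, rlrp_onset = 0),
      stim_effect)
  )
  if (any(p$cnv_amp > 0)) stopf("cnv_amp must be <= 0 (negative-going CNV)")
  if (p$lrp_amp > 0) stopf("lrp_amp must be <= 0 (contralateral negativity)")
  if (any(c(p$rt_mu, p$rt_sigma, p$rt_tau) <= 0)) {
    stopf("ex-Gaussian RT parameters must be positive")
  }
  if (any(c(p$miss_rate, p$false_alarm_rate) < 0) ||
      any(c(p$miss_rate, p$false_alarm_rate) > 1)) {
    stopf("miss_rate and false_alarm_rate must be in [0, 1]")
  }
  if (any(p$rlrp_onset >= 0)) stopf("rlrp_onset is ms before the response (< 0)")
  if (p$noise_rms < 0 || p$line_amp < 0) stopf("noise amplitudes must be >= 0")
  # motor-template calibration anchor: the template is calibrated once at
  # these values; per-subject / stimulation onset variation is realized as
  # a time shift of the calibrated template
  p$anchor <- list(tlrp_onset = p$tlrp_onset, rlrp_onset = p$rlrp_onset,
                   rt_mu = p$rt_mu, rt_sigma = p$rt_sigma, rt_tau = p$rt_tau)
  structure(p, class = "subject_params")
}

# Additive stimulation shift for the active session.
apply_stim_effect <- function(params, stimulation) {
  if (stimulation != "active") return(params)
  se <- params$stim_effect
  params$rt_mu <- params$rt_mu + se$rt_mu
  params$cnv_amp <- pmin(params$cnv_amp + se$cnv_amp, 0)
  params$tlrp_onset <- params$tlrp_onset + se$tlrp_onset
  params$rlrp_onset <- pmin(params$rlrp_onset + se$rlrp_onset, -5)
  params
}

#' Cohort specification
#'
#' Describes a cohort of simulated participants: how many, an optional
#' between-subject group assignment (e.g. stimulated hemisphere), the two
#' stimulation sessions each participant completes (order counterbalanced
#' across participants), the between-subject parameter spread, and the master
#' seed from which all randomness derives.
#'
#' The spread model gives each participant a shared offset per parameter
#' class (amplitudes, onsets/latencies, RT location) plus a smaller
#' independent jitter per condition; ERP measures are strongly correlated
#' across conditions within a participant, and the study's printed
#' cue-effect F statistics imply cue-difference spreads far smaller than
#' cell spreads, which is exactly what the shared-offset structure produces.
#'
#' @param n_subjects number of participants (>= 2).
#' @param group_assignment optional character vector, one between-subject
#'   level per participant (e.g. `"dominant"`/`"non-dominant"`).
#' @param sessions the two stimulation labels; order is counterbalanced.
#' @param between_subject_sd named list of spreads: `amp_shared`, `amp_cond`
#'   (uV), `onset_shared`, `onset_cond`, `rt_shared`, `rt_cond` (ms).
#' @param seed master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 23, group_assignment = NULL,
                        sessions = c("active", "sham"),
                        between_subject_sd = list(),
                        seed = 1) {
  if (length(unique(sessions)) != 2) {
    stopf("each subject completes exactly two sessions with distinct labels")
  }
  if (!is.null(group_assignment)) {
    if (length(group_assignment) != n_subjects) {
      stopf("group_assignment must have one level per subject")
    }
    if (n_subjects < 2 || min(table(group_assignment)) < 1) {
      stopf("between-subject design needs at least one subject per group")
    }
    if (length(unique(group_assignment)) > 1 && n_subjects < 2) {
      stopf("no between-group contrast possible with < 2 subjects")
    }
  }
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  sd_def <- list(amp_shared = 1.5, amp_cond = 0.5,
                 onset_shared = 20, onset_cond = 6,
                 rt_shared = 50, rt_cond = 10)
  structure(list(
    n_subjects = n_subjects,
    group_assignment = group_assignment,
    sessions = sessions,
    between_subject_sd = utils::modifyList(sd_def, between_subject_sd),
    seed = seed
  ), class = "cohort_spec")
}

#' Draw one participant's parameters around a cohort base
#'
#' Applies the cohort spread model (shared per-subject offset plus
#' per-condition jitter, per parameter class) to `base`, with physiological
#' clamps: CNV and motor amplitudes stay negative, P300 positive, RT location
#' above 150 ms, onsets inside their measurement windows.
#'
#' @param base a [subject_params()].
#' @param sd between-subject spread list (see [cohort_spec()]).
#' @param seed integer seed for this participant.
#' @return a `subject_params` object.
#' @export
draw_subject_params <- function(base, sd, seed) {
  with_seed(seed, {
    jit <- function(x, shared, cond) x + stats::rnorm(1, 0, shared) +
      stats::rnorm(length(x), 0, cond)
    p <- base
    p$cnv_amp <- pmin(jit(base$cnv_amp, sd$amp_shared, sd$amp_cond), -0.5)
    p$p300_amp <- pmax(jit(base$p300_amp, sd$amp_shared, sd$amp_cond), 0.5)
    p$p300_lat <- pmin(pmax(jit(base$p300_lat, sd$onset_shared, sd$onset_cond),
                            220), 620)
    p$lrp_amp <- min(jit(base$lrp_amp, sd$amp_shared / 2, 0), -1)
    p$tlrp_onset <- pmin(pmax(jit(base$tlrp_onset, sd$onset_shared,
                                  sd$onset_cond), 150), 500)
    p$rlrp_onset <- pmin(pmax(jit(base$rlrp_onset, sd$onset_shared / 2,
                                  sd$onset_cond), -250), -60)
    p$rt_mu <- pmax(jit(base$rt_mu, sd$rt_shared, sd$rt_cond), 150)
    p
  })
}

# Session plan: one row per subject x session, with per-session seeds and
# counterbalanced session order (odd subjects active first).
cohort_plan <- function(spec) {
  grp <- spec$group_assignment %||% rep("all", spec$n_subjects)
  rows <- lapply(seq_len(spec$n_subjects), function(s) {
    order_flip <- s %% 2 == 0
    sess <- if (order_flip) rev(spec$sessions) else spec$sessions
    data.frame(subject = sprintf("S%02d", s), subject_idx = s,
               group = grp[s], session = seq_along(sess),
               stimulation = sess,
               seed = vapply(seq_along(sess), function(k)
                 split_seed(spec$seed, s, k), integer(1)),
               param_seed = split_seed(spec$seed, s, 999L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
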