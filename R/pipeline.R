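#' Experiment profiles
#'
#' Bundled task and generator settings for the two study designs: `"exp1"`
#' (young adults, n = 23, ITI mean 2000 ms jittered 1500-2500 ms, P300
#' window 200-500 ms post-target) and `"exp2"` (older adults, n = 37 with a
#' between-subjects stimulated-hemisphere factor, 21 dominant / 16
#' non-dominant, ITI mean 3000 ms jittered 2500-3500 ms, P300 window
#' 250-650 ms). Generator component means are the corresponding printed
#' condition means; dispersion defaults are package conventions (methods
#' vignette).
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return list with `task`, `base_params`, `p300_window`, `n_subjects`,
#'   `group_assignment`, `between`.
#' @export
experiment_profile <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  if (name == "exp1") {
    list(
      name = "exp1",
      task = task_config(iti_mean = 2000, iti_min = 1500, iti_max = 2500),
      base_params = subject_params(),  # young-adult defaults
      p300_window = c(200, 500),
      n_subjects = 23,
      group_assignment = NULL,
      between = NULL
    )
  } else {
    list(
      name = "exp2",
      task = task_config(iti_mean = 3000, iti_min = 2500, iti_max = 3500),
      base_params = subject_params(
        cnv_amp = c(-5.9, -4.3),
        p300_amp = c(14.6, 17.2), p300_lat = c(450, 455),
        tlrp_onset = c(340.1, 381.3), rlrp_onset = c(-118.6, -163.5),
        rt_mu = c(433, 427, 513, 504)),
      p300_window = c(250, 650),
      n_subjects = 37,
      group_assignment = rep(c("dominant", "non-dominant"), c(21, 16)),
      between = "hemisphere"
    )
  }
}

#' Assemble a full run configuration
#'
#' Collects everything one reproducible run needs: the experiment profile
#' (with optional overrides for cohort size, trials per block, sampling
#' rate, montage, noise, spread, and the injected stimulation effect),
#' preprocessing parameters, component measurement specs, and the
#' statistics settings. `trials_per_block` below the profile's 80 scales
#' the run down without touching the task's structure (block composition,
#' nogo proportion, timing).
#'
#' @param profile `"exp1"` or `"exp2"`.
#' @param n_subjects cohort size override.
#' @param trials_per_block trials per block override.
#' @param fs synthesis sampling rate, Hz.
#' @param montage a montage or a [standard_montage()] name.
#' @param seed master seed.
#' @param stim_effect stimulation-shift list forwarded to
#'   [subject_params()] (default zero = true null).
#' @param noise_rms background-noise RMS override, uV.
#' @param between_subject_sd spread overrides (see [cohort_spec()]).
#' @param band,notch,artifact_threshold,exclusion_fraction preprocessing
#'   parameters.
#' @param draws,run_bf,bf_measures Bayes-factor settings (`run_bf = FALSE`
#'   skips model comparison).
#' @param cache_dir optional directory for caching the measure table by
#'   config hash.
#' @return a `run_config` list.
#' @export
run_config <- function(profile = "exp1", n_subjects = NULL,
                       trials_per_block = NULL, fs = 128,
                       montage = "basic", seed = 1,
                       stim_effect = list(), noise_rms = NULL,
                       between_subject_sd = list(),
                       band = c(0.02, 30), notch = 50,
                       artifact_threshold = 100, exclusion_fraction = 0.4,
                       draws = 2000, run_bf = TRUE,
                       bf_measures = c("rt", "cnv"), cache_dir = NULL) {
  prof <- experiment_profile(profile)
  if (!is.null(trials_per_block)) {
    prof$task$trials_per_block <- trials_per_block
  }
  n_subjects <- n_subjects %||% prof$n_subjects
  grp <- prof$group_assignment
  if (!is.null(grp) && n_subjects != length(grp)) {
    grp <- rep(unique(grp), length.out = n_subjects)  # keep both groups
    grp <- sort(grp)
  }
  params <- prof$base_params
  params$stim_effect <- utils::modifyList(params$stim_effect, stim_effect)
  if (!is.null(noise_rms)) params$noise_rms <- noise_rms
  if (is.character(montage)) montage <- standard_montage(montage)
  cfg <- list(
    profile = prof$name,
    task = prof$task,
    base_params = params,
    cohort = cohort_spec(n_subjects, grp,
                         between_subject_sd = between_subject_sd,
                         seed = seed),
    between = prof$between,
    montage = montage, fs = fs, seed = seed,
    band = band, notch = notch,
    artifact_threshold = artifact_threshold,
    exclusion_fraction = exclusion_fraction,
    specs = list(
      component_spec("CNV", "Cz", c(prof$task$cue_dur - 200,
                                    prof$task$cue_dur),
                     "mean_amplitude", "negative"),
      component_spec("P300", "Pz", prof$p300_window, "peak", "positive"),
      component_spec("tLRP", NA, c(100, 600), "fractional_area_latency",
                     "negative", fraction = 0.25),
      component_spec("rLRP", NA, c(-300, -100), "fractional_area_latency",
                     "negative", fraction = 0.25)),
    draws = draws, run_bf = run_bf, bf_measures = bf_measures,
    cache_dir = cache_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks montage completeness, window containment in the epoch windows the
#' pipeline extracts, Nyquist constraints, and factor/measure compatibility
#' (LRP measures carry no hand factor). Returns `TRUE` invisibly or stops
#' with the aggregated error list.
#'
#' @param config a [run_config()].
#' @return `TRUE` (invisibly) if valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  tryCatch(validate_montage(config$montage),
           error = function(e) errs <<- c(errs, conditionMessage(e)))
  if (config$band[2] >= config$fs / 2) {
    errs <- c(errs, sprintf("band edge %g Hz >= Nyquist", config$band[2]))
  }
  cue_epoch <- c(-800, config$task$cue_dur + 800)
  for (sp in config$specs) {
    win <- sp$window
    ok <- switch(sp$name,
                 CNV = win[1] >= cue_epoch[1] && win[2] <= cue_epoch[2],
                 P300 = win[1] >= -200 && win[2] <= 800,
                 tLRP = win[1] >= -200 && win[2] <= 800,
                 rLRP = win[1] >= -800 && win[2] <= 200,
                 TRUE)
    if (!ok) {
      errs <- c(errs, sprintf("%s window [%g, %g] outside its epoch",
                              sp$name, win[1], win[2]))
    }
    if (sp$name %in% c("tLRP", "rLRP") && !is.na(sp$channel)) {
      errs <- c(errs,
                sprintf("%s is defined on the C3/C4 pair; a channel key is invalid",
                        sp$name))
    }
  }
  if (length(errs)) {
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Preprocess one session: signal chain to condition-averaged waveforms
#'
#' Re-references to average mastoids, band-pass and notch filters, extracts
#' cue-locked (-800..2300 ms, baseline 200 ms before fixation), target-locked
#' (-200..800 ms, 200 ms pre-target baseline) and response-locked
#' (-800..200 ms, baseline -700..-500 ms) epochs, marks artifact trials,
#' averages correct go trials per cue x hand cell, and derives the per-cue
#' target- and response-locked LRP waveforms (30 Hz zero-phase low-passed).
#'
#' @param rec a raw [continuous_recording()].
#' @param config a [run_config()].
#' @param stimulation session label for the metadata.
#' @return a `session_waveforms` list: `cue_locked`, `target_locked`,
#'   `lrp_target`, `lrp_response` (waveform sets), `behavior` (epoch set
#'   for behavioral measures), `reject_fraction`.
#' @export
prepare_session <- function(rec, config, stimulation = NA_character_) {
  rec <- rereference_mastoids(rec)
  # mastoids carry no further information after re-referencing
  rec <- filter_recording(rec, config$band, config$notch,
                          channels = scalp_channels(rec$montage))
  cue_end <- config$task$cue_dur + 800

  ep_cue <- extract_epochs(rec, "cue", -800, cue_end, stimulation)
  ep_cue <- baseline(ep_cue, c(-700, -500))
  ep_cue <- reject_artifacts(ep_cue, config$artifact_threshold)

  ep_tgt <- extract_epochs(rec, "target", -200, 800, stimulation)
  ep_tgt <- baseline(ep_tgt, c(-200, 0))
  ep_tgt <- reject_artifacts(ep_tgt, config$artifact_threshold)

  ep_rsp <- extract_epochs(rec, "response", -800, 200, stimulation)
  ep_rsp <- baseline(ep_rsp, c(-700, -500))
  ep_rsp <- reject_artifacts(ep_rsp, config$artifact_threshold)

  go_ok <- function(ep) !ep$meta$is_nogo & ep$meta$correct &
    !is.na(ep$meta$hand)
  cue_avg <- average_condition(ep_cue, c("cue", "hand"), go_ok(ep_cue))
  tgt_avg <- average_condition(ep_tgt, c("cue", "hand"), go_ok(ep_tgt))
  rsp_avg <- average_condition(ep_rsp, c("cue", "hand"), go_ok(ep_rsp))

  fs <- rec$fs
  lrp_from <- function(avg) {
    out <- list()
    for (cu in CUES) {
      out[[cu]] <- lowpass_lrp(
        derive_lrp(avg[[paste(cu, "left", sep = "|")]],
                   avg[[paste(cu, "right", sep = "|")]]), 30, fs)
    }
    out
  }
  list(cue_locked = cue_avg, target_locked = tgt_avg,
       lrp_target = lrp_from(tgt_avg), lrp_response = lrp_from(rsp_avg),
       behavior = ep_cue,
       reject_fraction = mean(ep_cue$reject))
}

#' Measure one session
#'
#' Runs [measure_all()] and [behavioral_measures()] on a prepared session.
#'
#' @param prep a [prepare_session()] result.
#' @param config a [run_config()].
#' @param subject,group,stimulation identifiers.
#' @return long-format measure rows.
#' @export
measure_session <- function(prep, config, subject, group, stimulation) {
  rbind(
    measure_all(prep, config$specs, subject, group, stimulation),
    behavioral_measures(prep$behavior, subject, group))
}

# Factor sets per measure: LRP onsets carry no hand factor.
measure_factors <- function(measure, between = NULL) {
  w <- if (measure %in% c("tlrp", "rlrp")) c("stimulation", "cue")
  else c("stimulation", "cue", "hand")
  list(within = w, between = between)
}

#' Run a configured experiment end to end
#'
#' Simulates the cohort session by session (streaming: recordings are not
#' retained), preprocesses and measures each session, excludes subjects
#' whose rejected-epoch fraction exceeds the configured limit, then runs
#' the repeated-measures (or mixed, for a between-subjects profile) ANOVA
#' per measure and, optionally, Bayes-factor model comparison for the
#' configured measures. Fully deterministic given the config's seed.
#'
#' @param config a [run_config()].
#' @param verbose print per-subject progress.
#' @return list with `measures` (long table), `anova` (per measure),
#'   `bf` (per configured measure), `exclusions`, `manifest`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  validate_config(config)
  cache_file <- NULL
  if (!is.null(config$cache_dir)) {
    dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(config$cache_dir,
                            sprintf("measures_%s.csv", config_hash(
                              config[setdiff(names(config),
                                             c("cache_dir", "draws",
                                               "run_bf", "bf_measures"))])))
  }
  exclusions <- data.frame(subject = character(), reason = character())
  if (!is.null(cache_file) && file.exists(cache_file)) {
    measures <- read_measures(cache_file)
  } else {
    plan <- cohort_plan(config$cohort)
    rows <- list()
    reject_frac <- stats::setNames(numeric(0), character(0))
    for (i in seq_len(nrow(plan))) {
      row <- plan[i, ]
      p <- draw_subject_params(config$base_params,
                               config$cohort$between_subject_sd,
                               row$param_seed)
      p <- apply_stim_effect(p, row$stimulation)
      sched <- make_schedule(config$task, seed = row$seed)
      rec <- simulate_subject(sched, p, config$montage, config$fs,
                              seed = row$seed)
      prep <- prepare_session(rec, config, row$stimulation)
      rows[[i]] <- measure_session(prep, config, row$subject, row$group,
                                   row$stimulation)
      prev <- if (row$subject %in% names(reject_frac))
        reject_frac[[row$subject]] else 0
      reject_frac[row$subject] <- max(prev, prep$reject_fraction)
      if (verbose) {
        message(sprintf("  %s session %d (%s): %.0f%% epochs rejected",
                        row$subject, row$session, row$stimulation,
                        100 * prep$reject_fraction))
      }
    }
    measures <- do.call(rbind, rows)
    excl <- names(reject_frac)[reject_frac > config$exclusion_fraction]
    if (length(excl)) {
      exclusions <- data.frame(
        subject = excl,
        reason = sprintf("rejected-epoch fraction > %.0f%%",
                         100 * config$exclusion_fraction))
      measures <- measures[!measures$subject %in% excl, ]
    }
    if (!is.null(cache_file)) {
      utils::write.csv(measures, cache_file, row.names = FALSE)
    }
  }

  between <- if (!is.null(config$between)) "group" else NULL
  erp_measures <- c("rt", "cnv", "p300_amp", "p300_lat", "tlrp", "rlrp")
  # a subject with an undefined onset estimate in any cell of a measure
  # cannot enter that measure's balanced analysis
  complete_for <- function(m) {
    sub <- measures[measures$measure == m, ]
    bad <- unique(sub$subject[is.na(sub$value)])
    sub[!sub$subject %in% bad, ]
  }
  anova <- list()
  for (m in intersect(erp_measures, unique(measures$measure))) {
    sub <- complete_for(m)
    fac <- measure_factors(m, between)
    anova[[m]] <- rm_anova(sub, within = fac$within, between = fac$between)
  }

  bf <- list()
  if (isTRUE(config$run_bf)) {
    for (m in intersect(config$bf_measures, names(anova))) {
      sub <- complete_for(m)
      fac <- measure_factors(m, between)
      bf[[m]] <- model_comparison(sub, c(fac$within, fac$between),
                                  draws = config$draws,
                                  seed = split_seed(config$seed, 77L,
                                                    match(m, erp_measures)))
    }
  }

  manifest <- list(
    profile = config$profile, seed = config$seed,
    n_subjects = config$cohort$n_subjects,
    trials_per_block = config$task$trials_per_block,
    fs = config$fs,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("gonogoerp")),
    r_version = R.version.string)

  list(measures = measures, anova = anova, bf = bf,
       exclusions = exclusions, manifest = manifest)
}
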