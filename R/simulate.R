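# --- component templates (continuous time, ms) -------------------------------
#
# Template shapes are half-cosine ramps and Gaussian-windowed peaks. Only
# their window-aggregated amplitudes and fractional-area onsets are
# contractually meaningful; the generator scales/places each template so the
# measurement pipeline recovers the configured parameter exactly on noiseless
# data.

# CNV: 0 before `onset` (ms post-cue), half-cosine rise to 1 at `peak`
# (= target onset), half-cosine decay back to 0 over `decay` ms.
cnv_shape <- function(t, onset, peak, decay = 400) {
  y <- numeric(length(t))
  rise <- t >= onset & t < peak
  y[rise] <- 0.5 * (1 - cos(pi * (t[rise] - onset) / (peak - onset)))
  fall <- t >= peak & t < peak + decay
  y[fall] <- 0.5 * (1 + cos(pi * (t[fall] - peak) / decay))
  y
}

# Scale factor so that the mean of the scaled CNV template over the
# measurement window (ms post-cue) equals `amp`.
cnv_scale <- function(amp, onset, peak, window, decay = 400) {
  tt <- seq(window[1], window[2], by = 0.5)
  amp / mean(cnv_shape(tt, onset, peak, decay))
}

# P300: Gaussian bump, peak 1 at `lat` ms post-target.
p300_shape <- function(t, lat, width) exp(-(t - lat)^2 / (2 * width^2))

# Lateralized motor potential, target-locked time base: zero before `start`,
# power rise ((t-start)/(peak-start))^curv to 1 at `peak`, half-cosine decay
# over `decay` ms after it. The peak precedes the overt keypress (motor
# activation peaks around EMG onset).
motor_shape <- function(t, start, peak, curv, decay = 80) {
  y <- numeric(length(t))
  rise <- t >= start & t < peak
  y[rise] <- ((t[rise] - start) / (peak - start))^curv
  fall <- t >= peak & t < peak + decay
  y[fall] <- 0.5 * (1 + cos(pi * (t[fall] - peak) / decay))
  y
}

# Scalp projection weights per component (relative to the named channel).
# CNV is centro-medial (absent at Pz so the pre-target P300 baseline stays
# clean); P300 is parietal; the motor potential is C3/C4 with mild spread to
# the vertex. Weights at C3/C4 are hand-symmetric, so they cancel in the LRP
# double subtraction.
topo_weights <- function(component, channels, contra = NULL) {
  w <- stats::setNames(numeric(length(channels)), channels)
  put <- function(ch, val) {
    hit <- intersect(ch, channels)
    w[hit] <<- pmax(w[hit], val)
  }
  switch(component,
    cnv = { put("Cz", 1); put(c("FCz", "CPz"), 0.6)
            put(c("C3", "C4", "C1", "C2"), 0.3) },
    p300 = { put("Pz", 1); put(c("CPz", "POz", "P1", "P2"), 0.5) },
    motor = { put(contra, 1)
              put("Cz", 0.3) },
    stopf("unknown component '%s'", component))
  w
}

# --- background noise ---------------------------------------------------------

#' Generate 1/f^alpha Gaussian noise
#'
#' Spectral synthesis: Gaussian random spectrum shaped by f^(-alpha/2),
#' inverse FFT, rescaled to the requested RMS. The DC bin is zeroed.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param rms target root-mean-square amplitude, uV.
#' @param alpha spectral exponent (1 = pink noise).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
noise_1f <- function(n, fs, rms, alpha = 1, seed = 1) {
  if (rms <= 0) return(numeric(n))
  with_seed(seed, {
    nfft <- stats::nextn(n, 2)
    freqs <- seq(0, fs / 2, length.out = nfft / 2 + 1)
    shape <- c(0, freqs[-1]^(-alpha / 2))
    half <- (stats::rnorm(nfft / 2 + 1) + 1i * stats::rnorm(nfft / 2 + 1)) * shape
    half[1] <- 0
    half[nfft / 2 + 1] <- Re(half[nfft / 2 + 1])
    spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
    x * (rms / stats::sd(x))
  })
}

# --- motor-template calibration ----------------------------------------------
#
# The motor pulse is response-locked, as motor activation is: it rises from
# `start` (ms before the response) to a peak shortly before the keypress
# (around EMG onset) and decays over `decay` ms. Two fractional-area onsets
# constrain it:
#   * response-locked: the response-locked average is the pulse itself
#     (every trial contributes it in perfect alignment), so the rise start
#     is root-solved to make the pulse's 25% fractional-area onset over
#     [-300, -100] equal the configured rlrp_onset exactly;
#   * target-locked: the target-locked average is the pulse convolved with
#     the cue condition's RT distribution (the ex-Gaussian mixture over
#     hands), so the peak position is root-solved to make the *expected*
#     smeared average's onset over [100, 600] equal the configured
#     tlrp_onset.
# This RT-smearing geometry is exactly what makes printed values like
# tLRP 271 ms / mean RT 391 ms / rLRP -109 ms mutually consistent: no
# deterministic pulse identical in both frames can produce them (the
# early suprathreshold area required for the target-locked onset would
# drag the response-locked onset far earlier), but a response-locked pulse
# seen through RT variability can.

.motor_cache <- new.env(parent = emptyenv())

# The pipeline smooths the continuous data with the order-2 band-pass
# low-pass and the derived LRP with the order-4 low-pass; calibration
# applies the same pair.
motor_smooth <- function(x, fs, cutoff = 30) {
  lowpass_wave(lowpass_wave(x, fs, cutoff, order = 2), fs, cutoff, order = 4)
}

# ex-Gaussian density; degenerate parameters collapse to a point mass
rt_density <- function(rts, mu, sigma, tau) {
  if (sigma < 1 || tau < 1) {
    d <- numeric(length(rts))
    d[which.min(abs(rts - (mu + tau)))] <- 1
    return(d)
  }
  z <- (rts - mu) / sigma
  k <- sigma / tau
  d <- exp(-(rts - mu) / tau + k^2 / 2 - log(tau)) * stats::pnorm(z - k)
  d[!is.finite(d)] <- 0
  d
}

calibrate_motor <- function(tlrp_target, rlrp_target, rt_mu, rt_sigma, rt_tau,
                            fs, target_dur = 1000,
                            t_window = c(100, 600), r_window = c(-300, -100),
                            lp_cutoff = 30) {
  key <- paste(round(c(tlrp_target, rlrp_target, rt_mu, rt_sigma, rt_tau,
                       fs, target_dur), 2), collapse = "|")
  hit <- .motor_cache[[key]]
  if (!is.null(hit)) return(hit)

  times_r <- seq(ms_to_sample(-800, fs), ms_to_sample(200, fs)) / fs * 1000
  times_t <- seq(ms_to_sample(-200, fs), ms_to_sample(800, fs)) / fs * 1000
  # RT mixture over hands, matching the generator's truncation
  rts <- seq(120, target_dur + 400, by = 1000 / fs)
  dens <- rowMeans(vapply(seq_along(rt_mu), function(h)
    rt_density(rts, rt_mu[h], rt_sigma[h], rt_tau[h]), numeric(length(rts))))
  dens <- dens / sum(dens)

  fal_r <- function(start, peak, curv, dec) {
    wav <- motor_smooth(-motor_shape(times_r, start, peak, curv, dec), fs,
                        lp_cutoff)
    tryCatch(fractional_area_latency(wav, times_r, r_window, 0.25, "negative"),
             gonogoerp_undefined_latency = function(e) NA_real_)
  }
  # suprathreshold area of the pulse inside the response-locked window, per
  # unit amplitude: solutions with more in-window area give onset estimates
  # that are far more robust to background noise
  area_r <- function(start, peak, curv, dec) {
    wav <- motor_smooth(-motor_shape(times_r, start, peak, curv, dec), fs,
                        lp_cutoff)
    sel <- times_r >= r_window[1] & times_r <= r_window[2]
    v <- wav[sel]
    dev <- pmax(mean(v) - v, 0)
    sum(dev) * 1000 / fs
  }
  fal_t <- function(start, peak, curv, dec) {
    # expected target-locked average: pulse smeared by the RT distribution,
    # under the pipeline's 200 ms pre-target baseline (the fast-RT tail of
    # the smear is nonzero there)
    wav <- vapply(times_t, function(ti)
      -sum(motor_shape(ti - rts, start, peak, curv, dec) * dens), numeric(1))
    wav <- motor_smooth(wav, fs, lp_cutoff)
    wav <- wav - mean(wav[times_t >= -200 & times_t < 0])
    tryCatch(fractional_area_latency(wav, times_t, t_window, 0.25, "negative"),
             gonogoerp_undefined_latency = function(e) NA_real_)
  }
  # rise start making the response-locked onset exact, given (peak, curv,
  # dec); the onset is monotone in the rise start
  solve_start <- function(peak, curv, dec) {
    lo <- max(-295, rlrp_target - 160)
    hi <- peak - 25
    if (hi <= lo) return(NA_real_)
    g <- function(s) {
      v <- fal_r(s, peak, curv, dec)
      if (is.na(v)) return(1e3)  # no suprathreshold area: late-onset limit
      v - rlrp_target
    }
    glo <- g(lo); ghi <- g(hi)
    if (glo * ghi > 0) return(NA_real_)
    suppressWarnings(stats::uniroot(g, c(lo, hi), tol = 1e-4)$root)
  }
  cands <- list()
  for (curv in c(1, 1.5, 2, 3, 4)) {
    for (dec in c(60, 100)) {
      # peak position solved against the target-locked onset
      tl_err <- function(peak) {
        s <- solve_start(peak, curv, dec)
        if (is.na(s)) return(NA_real_)
        fal_t(s, peak, curv, dec) - tlrp_target
      }
      peaks <- seq(-140, -20, by = 15)
      errs <- vapply(peaks, tl_err, numeric(1))
      ok <- which(!is.na(errs))
      if (!length(ok)) next
      sgn <- which(diff(sign(errs[ok])) != 0)
      cand <- if (length(sgn)) {
        i <- ok[sgn[1]]; j <- ok[sgn[1] + 1]
        root <- suppressWarnings(
          stats::uniroot(tl_err, c(peaks[i], peaks[j]), tol = 1e-3)$root)
        list(peak = root, tl_err = tl_err(root))
      } else {
        i <- ok[which.min(abs(errs[ok]))]
        list(peak = peaks[i], tl_err = errs[i])
      }
      s <- solve_start(cand$peak, curv, dec)
      if (is.na(s)) next
      cands[[length(cands) + 1]] <- list(
        start = s, peak = cand$peak, curv = curv, decay = dec,
        fal_r = rlrp_target, fal_t = tlrp_target + cand$tl_err,
        tlrp_err = abs(cand$tl_err),
        area = area_r(s, cand$peak, curv, dec))
    }
  }
  if (!length(cands)) {
    stopf("motor-template calibration failed for tLRP %g / rLRP %g ms",
          tlrp_target, rlrp_target)
  }
  # among near-exact solutions prefer the most noise-robust one (largest
  # in-window response-locked area); otherwise minimize the residual
  errs <- vapply(cands, `[[`, 0, "tlrp_err")
  good <- which(errs <= pmax(1, min(errs)))
  best <- cands[[good[which.max(vapply(cands[good], `[[`, 0, "area"))]]]
  .motor_cache[[key]] <- best
  best
}

#' Ground-truth LRP onsets of the generator's motor template
#'
#' Returns the onset latencies the measurement pipeline recovers from a
#' noiseless recording for one cue condition: the response-locked onset is
#' the configured `rlrp_onset` (met exactly by calibration); the
#' target-locked onset is the configured `tlrp_onset` as realized on the
#' expected RT-smeared target-locked average (exact up to a small
#' calibration residual reported in `tlrp_err`, plus RT-sampling error in
#' finite cohorts). For parameters drawn around a cohort base, per-subject
#' and stimulation onset variation is realized as one shared time shift of
#' the calibrated pulse (the mean of the two onset offsets), and the
#' target-locked onset additionally follows the subject's mean-RT offset.
#'
#' @param params a [subject_params()].
#' @param cue `"directional"` or `"non-directional"`.
#' @param fs sampling rate used for synthesis, Hz.
#' @param target_dur target duration from the task, ms.
#' @return list with `tlrp`, `rlrp` (ms) and `tlrp_err` (calibration
#'   residual, ms).
#' @export
motor_ground_truth <- function(params, cue, fs = 128, target_dur = 1000) {
  anchor <- params$anchor
  cells <- paste(cue, HANDS, sep = ".")
  cal <- calibrate_motor(anchor$tlrp_onset[[cue]], anchor$rlrp_onset[[cue]],
                         anchor$rt_mu[cells], anchor$rt_sigma[cells],
                         anchor$rt_tau[cells], fs, target_dur)
  delta <- 0.5 * (params$tlrp_onset[[cue]] - anchor$tlrp_onset[[cue]]) +
    0.5 * (params$rlrp_onset[[cue]] - anchor$rlrp_onset[[cue]])
  rt_shift <- mean(params$rt_mu[cells] + params$rt_tau[cells]) -
    mean(anchor$rt_mu[cells] + anchor$rt_tau[cells])
  list(tlrp = cal$fal_t + delta + rt_shift, rlrp = cal$fal_r + delta,
       tlrp_err = cal$tlrp_err)
}

# --- subject simulation -------------------------------------------------------

#' Simulate one continuous recording from a trial schedule
#'
#' Builds a continuous multi-channel recording as the sum of (a) a cue-locked
#' CNV ramp at Cz (spread by fixed scalp weights), scaled so its mean over the
#' CNV measurement window equals `cnv_amp` for the trial's cue condition;
#' (b) a target-locked P300 bump at Pz on go trials; (c) a lateralized motor
#' potential at the electrode contralateral to the responding hand, shaped so
#' its measured fractional-area onsets equal `tlrp_onset`/`rlrp_onset`;
#' (d) 1/f^alpha noise plus a 50 Hz line sinusoid on every channel. Response
#' events are appended at target onset + ex-Gaussian RT on correct go trials;
#' omissions and false alarms are drawn at the configured rates. Nogo trials
#' carry the cue-locked CNV but no response and no motor potential.
#'
#' @param schedule a [make_schedule()] result.
#' @param params a [subject_params()].
#' @param montage a montage including Cz, Pz, C3, C4 and two mastoids.
#' @param fs synthesis sampling rate, Hz (>= 2x the highest synthesized
#'   frequency; the 50 Hz line term is dropped when `fs < 120`).
#' @param seed integer seed.
#' @return a [continuous_recording()] (reference state `"raw"`), with the
#'   per-trial ground truth attached as attribute `"trials"`.
#' @export
simulate_subject <- function(schedule, params, montage = standard_montage(),
                             fs = 128, seed = 1) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "subject_params"))
  validate_montage(montage)
  task <- attr(schedule, "task")
  channels <- names(montage)
  pad_start <- 2000
  n_tr <- nrow(schedule)

  # --- behavior: RTs, omissions, false alarms
  trials <- as.data.frame(schedule)
  trials$cue <- cue_condition(trials$block_type)
  beh <- with_seed(split_seed(seed, 7L), {
    resp_side <- ifelse(trials$is_nogo, trials$cue_side, trials$target_side)
    # non-directional nogo never occurs; go side always defined
    cell <- paste(trials$cue, resp_side, sep = ".")
    mu <- params$rt_mu[cell]; sg <- params$rt_sigma[cell]; tau <- params$rt_tau[cell]
    rt <- stats::rnorm(n_tr, mu, sg) + stats::rexp(n_tr, 1 / tau)
    rt <- pmin(pmax(round(rt), 120), task$target_dur + 400)
    miss <- stats::runif(n_tr) < params$miss_rate
    fa <- stats::runif(n_tr) < params$false_alarm_rate
    responded <- ifelse(trials$is_nogo, fa, !miss)
    list(rt = ifelse(responded, rt, NA_real_),
         resp_side = ifelse(responded, resp_side, NA_character_))
  })
  trials$rt <- beh$rt
  trials$resp_side <- beh$resp_side

  # --- event stream (recording clock = schedule clock + pad_start)
  ev <- list(data.frame(onset_ms = trials$t_fix + pad_start, code = "FIX"),
             data.frame(onset_ms = trials$t_cue + pad_start,
                        code = ifelse(trials$cue == "directional",
                                      ifelse(trials$cue_side == "left",
                                             "CUE_DIR_L", "CUE_DIR_R"),
                                      "CUE_NONDIR")),
             data.frame(onset_ms = trials$t_target + pad_start,
                        code = ifelse(trials$is_nogo, "TGT_NOGO",
                                      ifelse(trials$target_side == "left",
                                             "TGT_GO_L", "TGT_GO_R"))))
  has_resp <- !is.na(trials$rt)
  if (any(has_resp)) {
    ev <- c(ev, list(data.frame(
      onset_ms = trials$t_target[has_resp] + trials$rt[has_resp] + pad_start,
      code = ifelse(trials$resp_side[has_resp] == "left", "RESP_L", "RESP_R"))))
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onset_ms), ]

  dur_ms <- max(trials$t_target) + task$target_dur + task$iti_max +
    pad_start + 1000
  n_samp <- ms_to_sample(dur_ms, fs) + 1
  tgrid <- seq_len(n_samp) - 1  # sample indices; times = tgrid / fs * 1000

  data <- matrix(0, length(channels), n_samp, dimnames = list(channels, NULL))

  add_segment <- function(chan_w, event_ms, span, shape_fun) {
    i0 <- max(ms_to_sample(event_ms + span[1], fs), 0)
    i1 <- min(ms_to_sample(event_ms + span[2], fs), n_samp - 1)
    if (i1 < i0) return(invisible())
    rel <- sample_to_ms(i0:i1, fs) - event_ms
    y <- shape_fun(rel)
    for (ch in names(chan_w)[chan_w != 0]) {
      data[ch, (i0:i1) + 1] <<- data[ch, (i0:i1) + 1] + chan_w[ch] * y
    }
  }

  w_cnv <- topo_weights("cnv", channels)
  w_p300 <- topo_weights("p300", channels)
  cnv_win <- c(task$cue_dur - 200, task$cue_dur)  # ms post-cue
  scl <- vapply(CUES, function(cu)
    cnv_scale(params$cnv_amp[cu], params$cnv_onset, task$cue_dur, cnv_win),
    numeric(1))

  for (k in seq_len(n_tr)) {
    cu <- trials$cue[k]
    # CNV on every trial (go and nogo)
    add_segment(w_cnv * scl[cu], trials$t_cue[k] + pad_start,
                c(params$cnv_onset, task$cue_dur + 400),
                function(t) cnv_shape(t, params$cnv_onset, task$cue_dur))
    if (!trials$is_nogo[k]) {
      add_segment(w_p300 * params$p300_amp[cu],
                  trials$t_target[k] + pad_start,
                  params$p300_lat[cu] + c(-4, 4) * params$p300_width,
                  function(t) p300_shape(t, params$p300_lat[cu],
                                         params$p300_width))
    }
    if (!is.na(trials$rt[k])) {
      contra <- if (trials$resp_side[k] == "left") "C4" else "C3"
      # pulse calibrated once per cue at the cohort anchor and anchored to
      # this trial's response; subject/stimulation onset variation is one
      # shared time shift of the calibrated template
      anchor <- params$anchor
      cells <- paste(cu, HANDS, sep = ".")
      cal <- calibrate_motor(anchor$tlrp_onset[[cu]], anchor$rlrp_onset[[cu]],
                             anchor$rt_mu[cells], anchor$rt_sigma[cells],
                             anchor$rt_tau[cells], fs, task$target_dur)
      delta <- 0.5 * (params$tlrp_onset[[cu]] - anchor$tlrp_onset[[cu]]) +
        0.5 * (params$rlrp_onset[[cu]] - anchor$rlrp_onset[[cu]])
      add_segment(topo_weights("motor", channels, contra) * params$lrp_amp,
                  trials$t_target[k] + trials$rt[k] + pad_start + delta,
                  c(cal$start, cal$peak + cal$decay),
                  function(t) motor_shape(t, cal$start, cal$peak, cal$curv,
                                          cal$decay))
    }
  }

  if (params$noise_rms > 0) {
    for (j in seq_along(channels)) {
      data[j, ] <- data[j, ] + noise_1f(n_samp, fs, params$noise_rms,
                                        params$noise_exponent,
                                        split_seed(seed, 300L, j))
    }
  }
  if (params$line_amp > 0 && fs >= 120) {
    data <- data + matrix(params$line_amp *
                            sin(2 * pi * 50 * tgrid / fs), length(channels),
                          n_samp, byrow = TRUE)
  }

  rec <- continuous_recording(data, fs, channels, montage, events, "raw")
  attr(rec, "trials") <- trials
  rec
}

#' Generate a cohort of per-subject recordings
#'
#' Draws per-subject parameters around `base_params` with the cohort spread,
#' counterbalances session order, applies `stim_effect` in active sessions,
#' and simulates each subject x session recording. Fully reproducible from
#' the cohort seed.
#'
#' For large cohorts prefer [run_experiment()], which streams sessions
#' through the pipeline without holding all recordings in memory.
#'
#' @param spec a [cohort_spec()].
#' @param task a [task_config()].
#' @param base_params a [subject_params()].
#' @param montage,fs forwarded to [simulate_subject()].
#' @return list with one element per subject x session:
#'   `list(subject, group, session, stimulation, recording)`.
#' @export
generate_cohort <- function(spec, task, base_params,
                            montage = standard_montage(), fs = 128) {
  plan <- cohort_plan(spec)
  lapply(seq_len(nrow(plan)), function(i) {
    row <- plan[i, ]
    p <- draw_subject_params(base_params, spec$between_subject_sd,
                             row$param_seed)
    p <- apply_stim_effect(p, row$stimulation)
    sched <- make_schedule(task, seed = row$seed)
    rec <- simulate_subject(sched, p, montage, fs, seed = row$seed)
    list(subject = row$subject, group = row$group, session = row$session,
         stimulation = row$stimulation, recording = rec)
  })
}

#' Inject large-amplitude artifacts into a recording
#'
#' Adds square pulses of the given amplitude at the stated onsets on one
#' channel; used to exercise the artifact-rejection stage with known
#' contamination.
#'
#' @param rec a [continuous_recording()].
#' @param onsets_ms pulse onsets, ms.
#' @param amplitude pulse amplitude, uV.
#' @param channel channel label.
#' @param width_ms pulse width, ms.
#' @return the modified recording.
#' @export
inject_artifacts <- function(rec, onsets_ms, amplitude = 500,
                             channel = "Cz", width_ms = 50) {
  for (on in onsets_ms) {
    i0 <- ms_to_sample(on, rec$fs) + 1
    i1 <- min(i0 + ms_to_sample(width_ms, rec$fs), ncol(rec$data))
    rec$data[channel, i0:i1] <- rec$data[channel, i0:i1] + amplitude
  }
  rec
}
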