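#' Mean amplitude of a waveform over a window
#'
#' Arithmetic mean of the (baselined) condition-average waveform at one
#' channel over a closed window on its time base.
#'
#' @param erp an `erp_waveform` (see [average_condition()]).
#' @param channel channel label.
#' @param window ms pair within the epoch time base.
#' @return mean amplitude, uV.
#' @export
mean_amplitude <- function(erp, channel, window) {
  sel <- window_index(erp$times, window)
  mean(pick_channel(erp, channel)[sel])
}

#' Peak amplitude and latency within a window
#'
#' Extremum of the stated polarity within the closed window; the absolute
#' extremum is used (no local-maximum requirement) and window endpoints are
#' eligible. Ties are broken by the earliest sample.
#'
#' @param erp an `erp_waveform`.
#' @param channel channel label.
#' @param window ms pair.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum).
#' @return named numeric `c(amplitude, latency)` (uV, ms).
#' @export
peak_measure <- function(erp, channel, window,
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  sel <- window_index(erp$times, window)
  v <- pick_channel(erp, channel)[sel]
  i <- if (polarity == "positive") which.max(v) else which.min(v)
  c(amplitude = v[i], latency = erp$times[sel][i])
}

window_index <- function(times, window) {
  sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(sel)) {
    stopf("window [%g, %g] outside epoch time base [%g, %g]",
          window[1], window[2], min(times), max(times))
  }
  sel
}

pick_channel <- function(erp, channel) {
  if (!channel %in% rownames(erp$values)) {
    stopf("channel '%s' not present in waveform", channel)
  }
  erp$values[channel, ]
}

#' Derive the lateralized readiness potential (LRP)
#'
#' Double subtraction over the C3/C4 pair:
#' `LRP = 0.5 * [(C4 - C3) on left-hand trials + (C3 - C4) on right-hand
#' trials]`, pointwise on a shared time base. Correct-response motor
#' activation is negative under this convention; hand-symmetric activity
#' cancels.
#'
#' @param erp_left,erp_right `erp_waveform`s for left- and right-hand
#'   responses, each containing C3 and C4.
#' @return an `lrp_waveform`: list with `values` (uV), `times`,
#'   `n_left`, `n_right`, `zero_event`.
#' @export
derive_lrp <- function(erp_left, erp_right) {
  if (length(erp_left$times) != length(erp_right$times) ||
      max(abs(erp_left$times - erp_right$times)) > 1e-9) {
    stopf("left- and right-hand waveforms must share a time base")
  }
  lh <- erp_left$values["C4", ] - erp_left$values["C3", ]
  rh <- erp_right$values["C3", ] - erp_right$values["C4", ]
  structure(list(values = 0.5 * (lh + rh), times = erp_left$times,
                 n_left = erp_left$n_trials, n_right = erp_right$n_trials,
                 zero_event = erp_left$zero_event),
            class = "lrp_waveform")
}

#' Zero-phase low-pass filter an LRP waveform
#'
#' Order-4 Butterworth applied forward-backward (applied to the derived
#' subtraction waveform, after averaging); noiseless template latencies
#' shift by less than one sample.
#'
#' @param lrp an `lrp_waveform`.
#' @param cutoff cutoff frequency, Hz (< Nyquist).
#' @param fs sampling rate; inferred from the time base if omitted.
#' @return the filtered `lrp_waveform`.
#' @export
lowpass_lrp <- function(lrp, cutoff = 30, fs = NULL) {
  fs <- fs %||% (1000 / stats::median(diff(lrp$times)))
  lrp$values <- lowpass_wave(lrp$values, fs, cutoff)
  lrp
}

#' Fractional-area onset latency
#'
#' Onset estimation for component waveforms: the threshold is the mean
#' amplitude over the window; the suprathreshold signal is the portion of
#' the waveform beyond that threshold in the component's polarity direction
#' (more negative, for LRPs); its cumulative trapezoidal area is accumulated
#' across the window, and the returned latency is the linearly interpolated
#' time at which the cumulative area first reaches `fraction` of the total.
#'
#' The alternative reading -- area of the full waveform beyond zero, with the
#' window mean serving only as threshold -- is available as
#' `mode = "beyond_zero"`.
#'
#' @param wave numeric waveform values, or an `lrp_waveform`.
#' @param times time base in ms (ignored if `wave` is an `lrp_waveform`).
#' @param window ms pair (closed) within the time base.
#' @param fraction area fraction in (0, 1); 0.25 for onset latency.
#' @param polarity `"negative"` or `"positive"`.
#' @param mode suprathreshold convention (see above).
#' @return latency in ms (negative for response-locked pre-response onsets).
#'   If no suprathreshold area exists the error condition
#'   `gonogoerp_undefined_latency` is signalled.
#' @export
fractional_area_latency <- function(wave, times = NULL, window,
                                    fraction = 0.25,
                                    polarity = c("negative", "positive"),
                                    mode = c("beyond_mean", "beyond_zero")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  if (inherits(wave, "lrp_waveform")) {
    times <- wave$times
    wave <- wave$values
  }
  if (!(fraction > 0 && fraction < 1)) stopf("fraction must be in (0, 1)")
  sel <- window_index(times, window)
  t <- times[sel]; v <- wave[sel]
  thr <- if (mode == "beyond_mean") mean(v) else 0
  dev <- if (polarity == "negative") pmax(thr - v, 0) else pmax(v - thr, 0)
  # cumulative trapezoidal area
  dt <- diff(t)
  seg <- dt * (dev[-length(dev)] + dev[-1]) / 2
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {
    cond <- structure(class = c("gonogoerp_undefined_latency", "error",
                                "condition"),
                      list(message = "no suprathreshold area in window; onset latency undefined",
                           call = sys.call(-1)))
    stop(cond)
  }
  target <- fraction * total
  i <- which(cum >= target)[1]
  if (i == 1) return(t[1])
  t[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) * (t[i] - t[i - 1])
}

#' Component measurement specification
#'
#' Binds a named component to its channel(s), measurement window, baseline,
#' polarity and statistic (`mean_amplitude`, `peak`, or
#' `fractional_area_latency` with its area fraction).
#'
#' @param name one of `"CNV"`, `"P300"`, `"tLRP"`, `"rLRP"` (or a custom tag).
#' @param channel channel label (ignored for LRP statistics, which use the
#'   C3/C4 pair by construction).
#' @param window ms pair.
#' @param statistic measurement statistic.
#' @param polarity `"positive"` or `"negative"`.
#' @param fraction area fraction, latency statistic only.
#' @return a `component_spec`.
#' @export
component_spec <- function(name, channel, window,
                           statistic = c("mean_amplitude", "peak",
                                         "fractional_area_latency"),
                           polarity = "negative", fraction = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "fractional_area_latency") {
    fraction <- fraction %||% 0.25
    if (!(fraction > 0 && fraction < 1)) stopf("fraction must be in (0, 1)")
  } else if (!is.null(fraction)) {
    stopf("fraction is defined only for the latency statistic")
  }
  structure(list(name = name, channel = channel, window = window,
                 statistic = statistic, polarity = polarity,
                 fraction = fraction),
            class = "component_spec")
}

#' Measure all components of one session
#'
#' Applies a set of component specs to the session's condition-averaged
#' waveforms and returns long-format measure rows. CNV and P300 measures are
#' keyed by cue x hand; LRP onset rows are keyed by cue only (hand
#' `"collapsed"`: the double subtraction collapses hand by construction).
#'
#' @param waves a `session_waveforms` object (see [prepare_session()]):
#'   condition averages keyed `cue|hand` for the cue-locked and
#'   target-locked sets, and per-cue LRP waveforms (target- and
#'   response-locked).
#' @param specs list of [component_spec()]s.
#' @param subject,group,stimulation identifiers copied into the rows.
#' @return long-format measure rows
#'   (`subject, group, stimulation, cue, hand, measure, value`).
#' @export
measure_all <- function(waves, specs, subject = "S01", group = "all",
                        stimulation = NA_character_) {
  rows <- list()
  emit <- function(cue, hand, measure, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = subject, group = group, stimulation = stimulation,
      cue = cue, hand = hand, measure = measure, value = value,
      stringsAsFactors = FALSE)
  }
  for (sp in specs) {
    if (sp$name == "CNV") {
      for (nm in names(waves$cue_locked)) {
        cc <- strsplit(nm, "|", fixed = TRUE)[[1]]
        emit(cc[1], cc[2], "cnv",
             mean_amplitude(waves$cue_locked[[nm]], sp$channel, sp$window))
      }
    } else if (sp$name == "P300") {
      for (nm in names(waves$target_locked)) {
        cc <- strsplit(nm, "|", fixed = TRUE)[[1]]
        pk <- peak_measure(waves$target_locked[[nm]], sp$channel, sp$window,
                           sp$polarity)
        emit(cc[1], cc[2], "p300_amp", pk[["amplitude"]])
        emit(cc[1], cc[2], "p300_lat", pk[["latency"]])
      }
    } else if (sp$name == "tLRP") {
      for (cu in names(waves$lrp_target)) {
        emit(cu, "collapsed", "tlrp",
             fal_or_na(waves$lrp_target[[cu]], sp$window, sp$fraction,
                       sp$polarity))
      }
    } else if (sp$name == "rLRP") {
      for (cu in names(waves$lrp_response)) {
        emit(cu, "collapsed", "rlrp",
             fal_or_na(waves$lrp_response[[cu]], sp$window, sp$fraction,
                       sp$polarity))
      }
    } else {
      stopf("cannot resolve component spec '%s' against session waveforms",
            sp$name)
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(), group = character(),
                      stimulation = character(), cue = character(),
                      hand = character(), measure = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

fal_or_na <- function(lrp, window, fraction, polarity) {
  tryCatch(
    fractional_area_latency(lrp, window = window, fraction = fraction,
                            polarity = polarity),
    gonogoerp_undefined_latency = function(e) NA_real_)
}
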