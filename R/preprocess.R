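# --- filtering ----------------------------------------------------------------

# Zero-phase second-order notch (RBJ biquad) at `f0` with quality Q.
notch_coef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Single-pass IIR filter via the C loops in stats::filter (numerically
# identical to signal::filter for transfer-function coefficients, with far
# less call overhead).
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1), x), b,
                     method = "convolution", sides = 1)
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) v <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(v)
}

# Forward-backward application of one IIR filter with reflection padding to
# suppress edge transients on finite segments.
filtfilt_pad <- function(b, a, x, npad = NULL) {
  n <- length(x)
  npad <- min(npad %||% max(3 * (length(a) + length(b)), 24), n - 1)
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- rev(iir_filter(b, a, rev(iir_filter(b, a, c(left, x, right)))))
  y[(npad + 1):(npad + n)]
}

# Zero-phase low-pass used for LRP smoothing and template calibration.
lowpass_wave <- function(x, fs, cutoff, order = 4) {
  if (cutoff >= fs / 2) stopf("low-pass cutoff %g Hz >= Nyquist (%g Hz)",
                              cutoff, fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_pad(bf$b, bf$a, x)
}

#' Re-reference a recording to average mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#' Requires a raw (unreferenced) recording; re-referencing twice is rejected.
#'
#' @param rec a [continuous_recording()].
#' @return the re-referenced recording (`reference = "average-mastoid"`).
#' @export
rereference_mastoids <- function(rec) {
  if (rec$reference != "raw") {
    stopf("recording is already referenced (%s)", rec$reference)
  }
  mast <- mastoid_channels(rec$montage)
  mast <- intersect(mast, rec$channel_names)
  if (length(mast) != 2) {
    stopf("average-mastoid reference needs exactly 2 mastoid channels, found %d",
          length(mast))
  }
  ref <- colMeans(rec$data[mast, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref, "-")
  rec$reference <- "average-mastoid"
  rec
}

#' Band-pass and notch filter a continuous recording
#'
#' Applies, per channel and in zero-phase (forward-backward) form: a 50 Hz
#' second-order notch (Q = 30), an order-2 Butterworth high-pass at
#' `band[1]`, and an order-2 Butterworth low-pass at `band[2]` (a cascade
#' equivalent to a 4th-order band-pass but numerically robust at very low
#' high-pass edges). For recordings shorter than 60 s the high-pass edge is
#' numerically fragile and is replaced by linear detrending (flagged in the
#' returned recording's `"detrended"` attribute).
#'
#' @param rec a [continuous_recording()].
#' @param band band edges in Hz, default `c(0.02, 30)`.
#' @param notch notch frequency in Hz (`NULL` to skip), default 50.
#' @param channels optional channel subset to filter (default: all).
#' @return the filtered recording.
#' @export
filter_recording <- function(rec, band = c(0.02, 30), notch = 50,
                             channels = NULL) {
  fs <- rec$fs
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2]) {
    stopf("band edges (%g, %g) must satisfy 0 < low < high < Nyquist (%g)",
          band[1], band[2], fs / 2)
  }
  if (!is.null(notch) && notch >= fs / 2) {
    stopf("notch frequency %g Hz >= Nyquist (%g Hz)", notch, fs / 2)
  }
  short <- ncol(rec$data) / fs < 60
  lp <- signal::butter(2, band[2] / (fs / 2), type = "low")
  hp <- if (!short) signal::butter(2, band[1] / (fs / 2), type = "high")
  nc <- if (!is.null(notch)) notch_coef(notch, fs)
  rows <- if (is.null(channels)) seq_len(nrow(rec$data)) else
    which(rec$channel_names %in% channels)
  for (j in rows) {
    x <- rec$data[j, ]
    if (!is.null(nc)) x <- filtfilt_pad(nc$b, nc$a, x)
    if (short) {
      t <- seq_along(x)
      x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
    } else {
      x <- filtfilt_pad(hp$b, hp$a, x, npad = min(length(x) - 1, 2048))
    }
    rec$data[j, ] <- filtfilt_pad(lp$b, lp$a, x)
  }
  attr(rec, "detrended") <- short
  rec$band <- band
  rec
}

# --- epoching -----------------------------------------------------------------

# Parse the event stream into one row per trial with behavioral annotation
# (vectorized; called once per epoch extraction).
events_to_trials <- function(events) {
  trial <- cumsum(events$code == "FIX")
  if (max(trial) == 0) stopf("no FIX events in stream")
  keep <- trial > 0
  ev <- events[keep, , drop = FALSE]
  trial <- trial[keep]
  type <- substr(ev$code, 1, 3)
  ntr <- max(trial)
  # index of the first event of each type within each trial
  first_of <- function(tp) {
    idx <- which(type == tp)
    idx <- idx[!duplicated(trial[idx])]
    out <- rep(NA_integer_, ntr)
    out[trial[idx]] <- idx
    out
  }
  i_fix <- first_of("FIX"); i_cue <- first_of("CUE")
  i_tgt <- first_of("TGT"); i_rsp <- first_of("RES")
  code_at <- function(i) ifelse(is.na(i), NA_character_, ev$code[i])
  on_at <- function(i) ifelse(is.na(i), NA_real_, ev$onset_ms[i])
  cue_code <- code_at(i_cue); tgt_code <- code_at(i_tgt)
  rsp_code <- code_at(i_rsp)
  is_nogo <- !is.na(tgt_code) & tgt_code == "TGT_NOGO"
  target_side <- ifelse(tgt_code == "TGT_GO_L", "left",
                        ifelse(tgt_code == "TGT_GO_R", "right", NA_character_))
  resp_side <- ifelse(rsp_code == "RESP_L", "left",
                      ifelse(rsp_code == "RESP_R", "right", NA_character_))
  has_resp <- !is.na(rsp_code)
  side_match <- resp_side == target_side
  side_match[is.na(side_match)] <- FALSE
  data.frame(
    trial = seq_len(ntr),
    t_fix = on_at(i_fix), t_cue = on_at(i_cue), t_target = on_at(i_tgt),
    t_resp = on_at(i_rsp),
    cue = ifelse(!is.na(cue_code) & cue_code == "CUE_NONDIR",
                 "non-directional", "directional"),
    cue_side = ifelse(cue_code == "CUE_DIR_L", "left",
                      ifelse(cue_code == "CUE_DIR_R", "right", NA_character_)),
    is_nogo = is_nogo,
    target_side = target_side,
    hand = ifelse(is_nogo, resp_side, target_side),
    rt = on_at(i_rsp) - on_at(i_tgt),
    correct = ifelse(is_nogo, !has_resp, has_resp & side_match),
    false_alarm = is_nogo & has_resp,
    miss = !is_nogo & !has_resp,
    stringsAsFactors = FALSE)
}

#' Extract epochs time-locked to a named event
#'
#' Cuts per-trial windows `[t_start, t_end)` (ms, half-open, 0-based sample
#' indexing with sample = round(ms x fs / 1000)) around the trial's
#' fixation, cue, target or response onset, on a shared time base. Trial
#' metadata (cue condition, target type, responding hand, RT, correctness)
#' is populated from the event stream. Trials without the zero event
#' (e.g. nogo trials under response locking) and trials whose window exceeds
#' the recording are dropped, with counts recorded in attributes
#' `"n_no_zero_event"` and `"n_out_of_range"`.
#'
#' @param rec a (filtered) [continuous_recording()].
#' @param zero_event one of `"fixation"`, `"cue"`, `"target"`, `"response"`.
#' @param t_start,t_end epoch window in ms relative to the zero event.
#' @param stimulation optional session label copied into the metadata.
#' @return an `epoch_set`: list with `data` (trials x channels x time array),
#'   `times` (ms), `meta` (per-trial data.frame), `reject` (logical),
#'   `fs`, `montage`, `zero_event`.
#' @export
extract_epochs <- function(rec, zero_event = c("target", "fixation", "cue",
                                               "response"),
                           t_start, t_end, stimulation = NA_character_) {
  zero_event <- match.arg(zero_event)
  stopifnot(t_start < t_end)
  trials <- events_to_trials(rec$events)
  zero_ms <- switch(zero_event, fixation = trials$t_fix, cue = trials$t_cue,
                    target = trials$t_target, response = trials$t_resp)
  if (all(is.na(zero_ms))) {
    stopf("no '%s' events available for epoching", zero_event)
  }
  keep <- !is.na(zero_ms)
  n_no_zero <- sum(!keep)

  off0 <- ms_to_sample(t_start, rec$fs)
  n_t <- ms_to_sample(t_end, rec$fs) - off0
  idx0 <- ms_to_sample(zero_ms, rec$fs) + off0
  in_range <- !is.na(idx0) & idx0 >= 0 & (idx0 + n_t) <= ncol(rec$data)
  n_out <- sum(keep & !in_range)
  keep <- keep & in_range
  if (!any(keep)) stopf("no trials fit the requested epoch window")

  kept <- which(keep)
  data <- array(NA_real_, c(length(kept), nrow(rec$data), n_t),
                dimnames = list(NULL, rec$channel_names, NULL))
  for (i in seq_along(kept)) {
    cols <- (idx0[kept[i]] + 1):(idx0[kept[i]] + n_t)
    data[i, , ] <- rec$data[, cols]
  }
  meta <- trials[kept, , drop = FALSE]
  meta$stimulation <- stimulation
  rownames(meta) <- NULL
  structure(list(data = data, times = sample_to_ms(off0 + 0:(n_t - 1), rec$fs),
                 meta = meta, reject = rep(FALSE, length(kept)),
                 fs = rec$fs, montage = rec$montage, zero_event = zero_event,
                 baseline_interval = NULL),
            n_no_zero_event = n_no_zero, n_out_of_range = n_out,
            class = "epoch_set")
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the (half-open) baseline
#' interval. Idempotent; after correction the mean over the interval is zero
#' per channel.
#'
#' @param epochs an `epoch_set`.
#' @param interval ms pair within the epoch time base.
#' @return the baselined `epoch_set` (with `baseline_interval` recorded).
#' @export
baseline <- function(epochs, interval) {
  sel <- epochs$times >= interval[1] & epochs$times < interval[2]
  if (!any(sel)) {
    stopf("baseline interval [%g, %g) outside epoch time base [%g, %g]",
          interval[1], interval[2], min(epochs$times), max(epochs$times))
  }
  bl <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (dim 3)
  epochs$baseline_interval <- interval
  epochs
}

#' Mark artifact-contaminated epochs
#'
#' Sets the rejection mask wherever any scalp channel exceeds
#' `abs_threshold` in absolute value within the epoch. Mastoid channels are
#' ignored. Returns the epoch set with its `reject` mask updated (existing
#' marks are kept).
#'
#' @param epochs an `epoch_set`.
#' @param abs_threshold absolute amplitude threshold, uV (> 0).
#' @return the `epoch_set` with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, abs_threshold = 100) {
  if (abs_threshold <= 0) stopf("abs_threshold must be > 0")
  scalp <- intersect(scalp_channels(epochs$montage),
                     dimnames(epochs$data)[[2]])
  mx <- apply(abs(epochs$data[, scalp, , drop = FALSE]), 1, max)
  epochs$reject <- epochs$reject | mx > abs_threshold
  epochs
}

#' Average retained epochs within a condition cell
#'
#' Arithmetic mean over retained (non-rejected) trials matching `filter`,
#' split by the metadata columns in `by`. Empty cells raise an error naming
#' the cell.
#'
#' @param epochs an `epoch_set`.
#' @param by character vector of metadata columns defining the cells.
#' @param filter optional logical vector (length = trials) further
#'   restricting the trials (e.g. correct go trials only).
#' @return named list of `erp_waveform` objects (one per cell), each with
#'   `values` (channels x time, uV), `times`, `n_trials`, `condition`,
#'   `baseline_interval`.
#' @export
average_condition <- function(epochs, by, filter = NULL) {
  keep <- !epochs$reject
  requested <- rep(TRUE, length(keep))
  if (!is.null(filter)) {
    keep <- keep & filter
    requested <- filter
  }
  cells <- interaction(epochs$meta[by], drop = FALSE, sep = "|")
  out <- list()
  for (lv in levels(droplevels(cells[keep]))) {
    idx <- which(keep & cells == lv)
    out[[lv]] <- structure(list(
      values = colMeans(epochs$data[idx, , , drop = FALSE], dims = 1),
      times = epochs$times, n_trials = length(idx),
      condition = stats::setNames(strsplit(lv, "|", fixed = TRUE)[[1]], by),
      baseline_interval = epochs$baseline_interval,
      zero_event = epochs$zero_event),
      class = "erp_waveform")
  }
  if (!length(out)) stopf("no retained trials match the requested cells")
  # requested cells = the crossing of levels present among filtered trials;
  # a requested cell whose trials were all rejected is an error
  wanted <- levels(droplevels(interaction(
    epochs$meta[requested, by, drop = FALSE], drop = FALSE, sep = "|")))
  empty <- setdiff(wanted, names(out))
  if (length(empty)) {
    stopf("no retained trials in cell(s): %s", paste(empty, collapse = "; "))
  }
  out[wanted]
}

#' Behavioral measures per cue and hand
#'
#' From the trial metadata of an epoch set covering all trials: mean RT over
#' correct go trials per cue x hand cell, go omission rate per cue x hand,
#' and nogo false-alarm rate per cue (hand `"collapsed"`; nogo targets carry
#' no hand assignment).
#'
#' @param epochs an `epoch_set` whose metadata covers every trial
#'   (fixation-, cue- or target-locked).
#' @param subject,group identifiers copied into the rows.
#' @return long-format rows: `subject, group, stimulation, cue, hand,
#'   measure, value`.
#' @export
behavioral_measures <- function(epochs, subject = "S01", group = "all") {
  meta <- epochs$meta
  rows <- list()
  go <- meta[!meta$is_nogo, ]
  for (cu in unique(go$cue)) for (h in HANDS) {
    cell <- go[go$cue == cu & go$target_side == h, ]
    if (!nrow(cell)) next
    rows[[length(rows) + 1]] <- data.frame(
      subject = subject, group = group,
      stimulation = meta$stimulation[1], cue = cu, hand = h,
      measure = c("rt", "error_rate"),
      value = c(mean(cell$rt[cell$correct], na.rm = TRUE),
                mean(cell$miss)),
      stringsAsFactors = FALSE)
  }
  nogo <- meta[meta$is_nogo, ]
  if (nrow(nogo)) {
    for (cu in unique(nogo$cue)) {
      cell <- nogo[nogo$cue == cu, ]
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, group = group,
        stimulation = meta$stimulation[1], cue = cu, hand = "collapsed",
        measure = "false_alarm_rate", value = mean(cell$false_alarm),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
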