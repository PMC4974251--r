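EVENT_CODES <- c("FIX", "CUE_DIR_L", "CUE_DIR_R", "CUE_NONDIR",
                 "TGT_GO_L", "TGT_GO_R", "TGT_NOGO", "RESP_L", "RESP_R")

#' Continuous multi-channel recording
#'
#' Container for a continuous EEG recording: a channels x samples matrix in
#' uV, sampling rate, channel labels, montage roles, an ordered event stream
#' (`onset_ms`, `code`) and a reference-state tag (`"raw"` or
#' `"average-mastoid"`). Event onsets must be non-decreasing and lie within
#' the recording; channel labels must be unique and match the montage.
#'
#' @param data numeric matrix, channels x samples, uV.
#' @param fs sampling rate, Hz.
#' @param channel_names ordered channel labels (rownames of `data`).
#' @param montage a montage covering all channels.
#' @param events data.frame with columns `onset_ms`, `code`.
#' @param reference reference-state tag.
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_names, montage, events,
                                 reference = "raw") {
  stopifnot(is.matrix(data), fs > 0)
  if (length(channel_names) != nrow(data)) {
    stopf("channel_names length (%d) != number of data rows (%d)",
          length(channel_names), nrow(data))
  }
  if (anyDuplicated(channel_names)) stopf("channel names must be unique")
  extra <- setdiff(channel_names, names(montage))
  if (length(extra)) {
    stopf("channels absent from montage: %s", paste(extra, collapse = ", "))
  }
  rownames(data) <- channel_names
  events <- validate_events(events, duration_ms = ncol(data) / fs * 1000)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 montage = montage, events = events, reference = reference),
            class = "continuous_recording")
}

#' Validate an event stream
#'
#' Checks codes against the task's event vocabulary, onset ordering, bounds
#' against the recording duration, and that every response event follows a
#' target event within its trial (go or nogo: false alarms are responses to
#' nogo targets).
#'
#' @param events data.frame with `onset_ms`, `code`.
#' @param duration_ms recording duration; `NULL` skips the bound check.
#' @return the events, sorted, invisibly usable.
#' @export
validate_events <- function(events, duration_ms = NULL) {
  stopifnot(is.data.frame(events),
            all(c("onset_ms", "code") %in% names(events)))
  bad <- setdiff(unique(events$code), EVENT_CODES)
  if (length(bad)) {
    stopf("unknown event code(s) %s; valid codes: %s",
          paste(bad, collapse = ", "), paste(EVENT_CODES, collapse = ", "))
  }
  if (is.unsorted(events$onset_ms)) {
    events <- events[order(events$onset_ms), , drop = FALSE]
  }
  if (!is.null(duration_ms) && nrow(events)) {
    out <- events$onset_ms > duration_ms | events$onset_ms < 0
    if (any(out)) {
      stopf("event onset %.1f ms outside recording [0, %.1f] ms",
            events$onset_ms[which(out)[1]], duration_ms)
    }
  }
  # every RESP_* must be preceded by a TGT_* later than the last FIX
  is_resp <- startsWith(events$code, "RESP")
  if (any(is_resp)) {
    last_tgt <- -Inf; last_fix <- -Inf
    for (i in seq_len(nrow(events))) {
      code <- events$code[i]
      if (code == "FIX") last_fix <- events$onset_ms[i]
      if (startsWith(code, "TGT")) last_tgt <- events$onset_ms[i]
      if (startsWith(code, "RESP") && last_tgt < last_fix) {
        stopf("response event at %.1f ms has no target in its trial",
              events$onset_ms[i])
      }
    }
  }
  rownames(events) <- NULL
  events
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("continuous_recording: %d ch x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(utils::head(unique(x$events$code), 5), collapse = ", ")))
  invisible(x)
}

recording_duration_ms <- function(rec) ncol(rec$data) / rec$fs * 1000
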