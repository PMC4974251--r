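#' Write / read the on-disk bundle of a continuous recording
#'
#' A recording is stored as three documented text/binary files: the
#' continuous samples as 16-bit EDF, the event stream as a tab-separated
#' file with columns `onset_ms` and `code`, and the montage as a JSON
#' channel-to-role map. `read_recording` restores the
#' [continuous_recording()]; data round-trip within the EDF quantization
#' step, events and metadata exactly.
#'
#' @param rec a [continuous_recording()].
#' @param continuous_file EDF path.
#' @param event_file TSV path.
#' @param montage_file JSON path.
#' @return `write_recording`: the three paths, invisibly;
#'   `read_recording`: a `continuous_recording`.
#' @export
write_recording <- function(rec, continuous_file, event_file, montage_file) {
  write_edf(rec, continuous_file)
  write_events(rec$events, event_file)
  write_montage(rec$montage, montage_file)
  invisible(c(continuous_file, event_file, montage_file))
}

#' @rdname write_recording
#' @export
read_recording <- function(continuous_file, event_file, montage_file) {
  for (f in c(continuous_file, event_file, montage_file)) {
    if (!file.exists(f)) stopf("file not found: %s", f)
  }
  edf <- read_edf(continuous_file)
  montage <- read_montage(montage_file)
  extra <- setdiff(edf$channel_names, names(montage))
  if (length(extra)) {
    stopf("EDF channel(s) not in montage: %s", paste(extra, collapse = ", "))
  }
  events <- read_events(event_file)
  continuous_recording(edf$data, edf$fs, edf$channel_names, montage, events,
                       reference = "raw")
}

#' Write / read an event stream as tab-separated text
#'
#' Columns `onset_ms` (ms from recording start) and `code` (one of the task's
#' event codes). Reading validates codes and ordering.
#'
#' @param events data.frame with `onset_ms`, `code`.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("onset_ms", "code")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_events(ev)
}

#' Write the analysis tables of a run
#'
#' Emits the long-format measure table
#' (`subject, group, stimulation, cue, hand, measure, value`), one wide
#' cue-by-hand cell-mean (with SEM) summary per measure mirroring the
#' standard report layout, and the ANOVA and Bayes-factor tables.
#'
#' @param measures a long-format measure table (see [measure_all()]).
#' @param anova named list of ANOVA result tables, or `NULL`.
#' @param bf named list of Bayes-factor result tables, or `NULL`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_tables <- function(measures, anova = NULL, bf = NULL, out_dir) {
  if (is.null(measures) || !nrow(measures)) stopf("measure table is empty")
  key <- do.call(paste, c(measures[c("subject", "stimulation", "cue", "hand",
                                     "measure")], sep = "|"))
  if (anyDuplicated(key)) {
    stopf("duplicate (subject, stimulation, cue, hand, measure) rows: %s",
          key[anyDuplicated(key)])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, "measures.csv")
  utils::write.csv(measures, files[1], row.names = FALSE)
  for (m in unique(measures$measure)) {
    sub <- measures[measures$measure == m, ]
    wide <- summarize_cells(sub)
    f <- file.path(out_dir, sprintf("summary_%s.csv", m))
    utils::write.csv(wide, f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(anova %||% list())) {
    f <- file.path(out_dir, sprintf("anova_%s.csv", nm))
    utils::write.csv(as.data.frame(anova[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(bf %||% list())) {
    f <- file.path(out_dir, sprintf("bf_%s.csv", nm))
    utils::write.csv(as.data.frame(bf[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

# Cue x hand cell means with SEM per stimulation (x group) level, one row per
# group/stimulation, matching the standard condition-mean table layout.
summarize_cells <- function(sub) {
  cells <- split(sub$value, list(sub$group, sub$stimulation, sub$cue, sub$hand),
                 drop = TRUE, sep = "|")
  parts <- strsplit(names(cells), "|", fixed = TRUE)
  long <- data.frame(
    group = vapply(parts, `[`, "", 1),
    stimulation = vapply(parts, `[`, "", 2),
    cue = vapply(parts, `[`, "", 3),
    hand = vapply(parts, `[`, "", 4),
    mean = vapply(cells, mean, numeric(1)),
    sem = vapply(cells, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(cells, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(long) <- NULL
  long[order(long$group, long$stimulation, long$cue, long$hand), ]
}

#' Read a measure table written by [write_tables()]
#'
#' @param path path to `measures.csv`.
#' @return the long-format measure table.
#' @export
read_measures <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
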