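# Minimal EDF (European Data Format, 16-bit) writer/reader.
# No R EDF package is available in this stack, so the container format is
# implemented directly against the published header layout: 256-byte fixed
# header, 256 bytes per signal, then little-endian int16 data records with
# channel-sequential samples. Records are 1 s long; the exact sample count
# (which EDF cannot represent when the last record is padded) is stored in
# the reserved header field as "NS=<n>", which this reader honours.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write / read a continuous recording's samples as EDF
#'
#' 16-bit EDF with per-channel physical min/max set from the data range with
#' 5% headroom (quantization step `(pmax - pmin) / 65534`). Events and
#' montage are *not* part of EDF proper; see [write_recording()] for the
#' full bundle.
#'
#' @param rec a [continuous_recording()].
#' @param path output file.
#' @return `write_edf`: the path, invisibly. `read_edf`: a list with
#'   `data` (channels x samples, uV), `fs`, `channel_names`.
#' @export
write_edf <- function(rec, path) {
  data <- rec$data
  nch <- nrow(data); n <- ncol(data); fs <- rec$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  n_rec <- ceiling(n / fs)
  rng <- t(apply(data, 1, range))
  span <- pmax(rng[, 2] - rng[, 1], 1e-6)
  pmin_ <- rng[, 1] - 0.05 * span
  pmax_ <- rng[, 2] + 0.05 * span
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(pad_field(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256 + 256 * nch), 8)         # header bytes
  wr(sprintf("NS=%d", n), 44)                  # reserved: exact sample count
  wr(as.character(n_rec), 8)
  wr("1", 8)                                   # record duration, s
  wr(as.character(nch), 4)
  for (j in seq_len(nch)) wr(rec$channel_names[j], 16)
  for (j in seq_len(nch)) wr("", 80)           # transducer
  for (j in seq_len(nch)) wr("uV", 8)
  for (j in seq_len(nch)) wr(sprintf("%.7g", pmin_[j]), 8)
  for (j in seq_len(nch)) wr(sprintf("%.7g", pmax_[j]), 8)
  for (j in seq_len(nch)) wr(as.character(dmin), 8)
  for (j in seq_len(nch)) wr(as.character(dmax), 8)
  for (j in seq_len(nch)) wr("", 80)           # prefilter
  for (j in seq_len(nch)) wr(as.character(fs), 8)
  for (j in seq_len(nch)) wr("", 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  padded <- matrix(0, nch, n_rec * fs)
  padded[, seq_len(n)] <- data
  dig <- round((padded - pmin_) * scale + dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- t(dig[, cols, drop = FALSE])      # channel-sequential
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(j) rd(16), character(1))
  for (j in seq_len(nch)) rd(80)
  for (j in seq_len(nch)) rd(8)
  pmin_ <- vapply(seq_len(nch), function(j) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nch), function(j) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(j) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(j) as.numeric(rd(8)), numeric(1))
  for (j in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(j) as.integer(rd(8)), integer(1))
  for (j in seq_len(nch)) rd(32)

  if (length(unique(spr)) != 1) {
    stopf("reader supports uniform samples-per-record only")
  }
  total <- n_rec * spr[1]
  raw <- readBin(con, integer(), n = total * nch, size = 2, endian = "little")
  data <- matrix(0, nch, total)
  for (r in seq_len(n_rec)) {
    off <- (r - 1) * spr[1] * nch
    block <- matrix(raw[off + seq_len(spr[1] * nch)], spr[1], nch)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin_
  if (grepl("^NS=", reserved)) {
    n <- as.integer(sub("^NS=", "", reserved))
    data <- data[, seq_len(n), drop = FALSE]
  }
  rownames(data) <- labels
  list(data = data, fs = spr[1] / rec_dur, channel_names = labels)
}
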