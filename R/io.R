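# File interchange: WAV audio, EDF EEG, train sidecars and manifests.
# Both binary formats are written from scratch (RIFF PCM and EDF are simple,
# fully public layouts) so the package has no audio/EEG file dependencies.

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric samples; values are clipped to \[-1, 1\] and
#'   scaled to 16-bit integers.
#' @param fs Sampling rate (Hz).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(c(16)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(c(fs, fs * 2)), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] (PCM, mono, 16-bit).
#' @return List with `samples` (numeric in \[-1, 1\]) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_invalid("not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop_invalid("not a WAVE file: %s", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_invalid("no data chunk found")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) {
        stop_invalid("only mono PCM supported")
      }
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      ba_bits <- readBin(con, "integer", 2, 2, endian = "little")
      if (ba_bits[2] != 16) stop_invalid("only 16-bit supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      x <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                   endian = "little")
      return(list(samples = x / 32767, fs = fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}

#' Write a stimulus train to disk
#'
#' Writes the audio as WAV, the token onsets as a TSV sidecar
#' (`onset_s`, `token_kind`) and a JSON condition manifest.
#'
#' @param train A `stimulus_train`.
#' @param dir Output directory (created if needed).
#' @param stem File stem, default derived from the condition.
#' @return The manifest path, invisibly.
#' @export
write_train <- function(train, dir, stem = NULL) {
  stopifnot(inherits(train, "stimulus_train"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(stem)) {
    stem <- sprintf("%s_rate%.1f_jit%02.0f", train$kind, train$spec$rate,
                    100 * train$spec$jitter)
  }
  peak <- max(abs(train$audio))
  write_wav(train$audio / ifelse(peak > 0, peak, 1), train$fs,
            file.path(dir, paste0(stem, ".wav")))
  utils::write.table(
    data.frame(onset_s = train$onsets, token_kind = train$kind),
    file.path(dir, paste0(stem, "_events.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(stimulus = train$kind, rate_hz = train$spec$rate,
                   jitter_pct = 100 * train$spec$jitter,
                   n_tokens = train$spec$n_tokens, seed = train$spec$seed,
                   fs = train$fs)
  mp <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Write multichannel EEG as EDF
#'
#' European Data Format (EDF), 16-bit, one data record per second. Physical
#' units are microvolts; per-channel physical ranges are taken from the
#' data.
#'
#' @param eeg Channels x samples matrix (microvolts).
#' @param fs Sampling rate (Hz; must be an integer number of samples per
#'   1 s record).
#' @param channel_names One name per row.
#' @param path Output path.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, fs, channel_names, path,
                      patient = "X", recording = "synthetic") {
  eeg <- as.matrix(eeg)
  ns <- nrow(eeg)
  if (length(channel_names) != ns) stop_invalid("one name per channel needed")
  if (fs != round(fs)) stop_invalid("fs must be an integer for 1 s records")
  n_rec <- floor(ncol(eeg) / fs)
  if (n_rec < 1) stop_invalid("need at least 1 s of data")
  eeg <- eeg[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(eeg, 1, min); pmax_ <- apply(eeg, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(patient, 80), pad(recording, 80),
    pad(format(Sys.Date(), "01.01.00"), 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) {
    writeChar(paste0(vapply(vals, pad, character(1), w = w), collapse = ""),
              con, eos = NULL)
  }
  field(channel_names, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, format = "g", digits = 6), 8)
  field(formatC(pmax_, format = "g", digits = 6), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # re-read the ASCII ranges: scaling must match what a reader will parse
  pmin_r <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  gain <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      d <- round((eeg[ch, idx] - pmin_r[ch]) * gain[ch]) + dmin
      writeBin(as.integer(pmin(dmax, pmax(dmin, d))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the plain EDF layout written by [write_edf()]: equal sampling
#' rate across signals, contiguous records.
#'
#' @param path EDF file path.
#' @return List with `eeg` (channels x samples matrix, physical units),
#'   `fs`, `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8)                       # version
  readChar(con, 80); readChar(con, 80)   # patient, recording
  readChar(con, 8); readChar(con, 8)     # date, time
  readChar(con, 8)                       # header bytes
  readChar(con, 44)                      # reserved
  n_rec <- as.integer(readChar(con, 8))
  rec_dur <- as.numeric(readChar(con, 8))
  ns <- as.integer(readChar(con, 4))
  rd <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w)),
                           character(1))
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  if (length(unique(spr)) != 1) {
    stop_invalid("mixed sampling rates not supported")
  }
  fs <- spr[1] / rec_dur
  eeg <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", spr[1], 2, signed = TRUE,
                   endian = "little")
      eeg[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (d - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax_[ch] - pmin_[ch]) +
        pmin_[ch]
    }
  }
  list(eeg = eeg, fs = fs, channel_names = labels)
}

#' Match EDF channels to a montage by name
#'
#' Case-insensitive matching of recorded channel labels to the montage's
#' channel order; unmatched montage channels raise an error, extra recorded
#' channels are dropped with a warning.
#'
#' @param edf List from [read_edf()].
#' @param montage A `source_montage`.
#' @return Channels x samples matrix reordered to the montage rows.
#' @export
match_channels <- function(edf, montage) {
  idx <- match(tolower(montage$channel_names), tolower(edf$channel_names))
  if (anyNA(idx)) {
    stop_invalid("montage channel(s) missing from recording: %s",
                 paste(montage$channel_names[is.na(idx)], collapse = ", "))
  }
  dropped <- setdiff(seq_along(edf$channel_names), idx)
  if (length(dropped)) {
    warning(sprintf("dropping %d unmatched recorded channel(s): %s",
                    length(dropped),
                    paste(edf$channel_names[dropped], collapse = ", ")),
            call. = FALSE)
  }
  edf$eeg[idx, , drop = FALSE]
}
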