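#' Construct a source montage
#'
#' A montage couples a leadfield gain matrix (channels x sources, scalp
#' microvolts per nAm of source current) with channel names and source
#' labels. [apply_montage()] inverts it to recover source waveforms.
#'
#' @param leadfield Numeric matrix, channels x sources, full column rank.
#' @param channel_names Character vector, one per row.
#' @param source_labels Character vector, one per column.
#' @return A `source_montage` object.
#' @export
source_montage <- function(leadfield, channel_names, source_labels) {
  leadfield <- as.matrix(leadfield)
  if (nrow(leadfield) < ncol(leadfield)) {
    stop_invalid("leadfield needs at least as many channels as sources")
  }
  if (length(channel_names) != nrow(leadfield)) {
    stop_invalid("channel_names length != leadfield rows")
  }
  if (length(source_labels) != ncol(leadfield)) {
    stop_invalid("source_labels length != leadfield columns")
  }
  qr_l <- qr(leadfield)
  if (qr_l$rank < ncol(leadfield)) {
    bad <- source_labels[setdiff(seq_len(ncol(leadfield)),
                                 qr_l$pivot[seq_len(qr_l$rank)])]
    stop_invalid("leadfield is rank deficient; collinear source(s): %s",
                 paste(bad, collapse = ", "))
  }
  structure(
    list(leadfield = leadfield, channel_names = channel_names,
         source_labels = source_labels),
    class = "source_montage"
  )
}

#' Re-reference scalp EEG to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean is zero. Idempotent; removes any common-mode
#' offset.
#'
#' @param eeg Numeric matrix, channels x samples.
#' @return Re-referenced matrix of the same shape.
#' @export
rereference_common_average <- function(eeg) {
  eeg <- as.matrix(eeg)
  if (nrow(eeg) < 2) stop_invalid("need at least 2 channels to re-reference")
  sweep(eeg, 2, colMeans(eeg), "-")
}

#' Project scalp EEG into source space
#'
#' Applies the Moore-Penrose pseudoinverse of the montage leadfield to the
#' (common-average-referenced) EEG: `SWF = pinv(L) x EEG`. For a square
#' full-rank leadfield this is the exact inverse; for the usual tall case it
#' is the least-squares source estimate.
#'
#' @param eeg Numeric matrix, channels x samples; channel count must match
#'   the montage. A warning is issued if the data are not common-average
#'   referenced.
#' @param montage A `source_montage`.
#' @return A `source_waveforms` object: `currents` (sources x samples, nAm),
#'   `fs` attribute not tracked here, `labels`.
#' @export
apply_montage <- function(eeg, montage) {
  stopifnot(inherits(montage, "source_montage"))
  eeg <- as.matrix(eeg)
  if (nrow(eeg) != nrow(montage$leadfield)) {
    stop_invalid("EEG has %d channels but montage expects %d",
                 nrow(eeg), nrow(montage$leadfield))
  }
  if (max(abs(colMeans(eeg))) > 1e-6 * max(1, max(abs(eeg)))) {
    warning("EEG does not appear to be common-average referenced",
            call. = FALSE)
  }
  currents <- MASS::ginv(montage$leadfield) %*% eeg
  structure(
    list(currents = currents, labels = montage$source_labels),
    class = "source_waveforms"
  )
}

#' Extract an equal-length analysis segment
#'
#' Cuts `length` seconds starting at `start` seconds from source waveforms
#' (or any channels x samples matrix), so every condition contributes the
#' same amount of data.
#'
#' @param waves A `source_waveforms`, or a numeric matrix/vector.
#' @param fs Sampling rate (Hz).
#' @param start Segment start in seconds.
#' @param length Segment length in seconds (default 30).
#' @return Object of the same kind, trimmed; the chosen offsets are recorded
#'   in attributes `start` and `length`.
#' @export
extract_segment <- function(waves, fs, start = 0, length = 30) {
  x <- if (inherits(waves, "source_waveforms")) waves$currents else waves
  vec <- is.null(dim(x))
  n <- if (vec) base::length(x) else ncol(x)
  i0 <- as.integer(round(start * fs))
  ns <- as.integer(round(length * fs))
  if (i0 < 0 || i0 + ns > n) {
    stop_invalid("segment [%g, %g] s outside record of %.2f s",
                 start, start + length, n / fs)
  }
  idx <- (i0 + 1):(i0 + ns)
  out <- if (vec) x[idx] else x[, idx, drop = FALSE]
  if (inherits(waves, "source_waveforms")) {
    waves$currents <- out
    attr(waves, "start") <- start
    attr(waves, "length") <- length
    waves
  } else {
    attr(out, "start") <- start
    attr(out, "length") <- length
    out
  }
}
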