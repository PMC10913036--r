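#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal whose real part is the input and
#' whose modulus/argument give the Hilbert envelope and instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) stop_invalid("signal too short for analytic transform")
  # zero-pad to a highly composite length: R's fft degrades badly on
  # lengths with large prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(m - n))
  X <- fft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

#' Stimulus envelope at the EEG sampling rate
#'
#' Full-band Hilbert envelope of the audio, anti-alias low-passed below the
#' target Nyquist (zero-phase FFT-domain filter with a raised-cosine
#' transition band from 0.8 to 1.0 of the target Nyquist) and resampled onto
#' the target grid by linear interpolation. The result is clamped at zero:
#' an envelope is non-negative by construction and the filter's residual
#' Gibbs ripple may dip marginally below.
#'
#' @param audio Numeric audio samples.
#' @param fs_audio Audio sampling rate (Hz).
#' @param fs_target Output sampling rate (Hz), default 500 (EEG rate).
#' @return Envelope sampled at `fs_target`.
#' @export
stimulus_envelope <- function(audio, fs_audio, fs_target = 500) {
  if (fs_audio < fs_target) {
    stop_invalid("fs_audio (%g) must be >= fs_target (%g)", fs_audio, fs_target)
  }
  if (fs_audio < 2 * fs_target && fs_audio != fs_target) {
    stop_invalid("fs_audio must be >= 2 * fs_target for anti-aliased resampling")
  }
  if (all(audio == 0)) {
    n_out <- as.integer(round(length(audio) / fs_audio * fs_target))
    return(numeric(n_out))
  }
  env <- Mod(analytic_signal(audio))
  if (fs_audio == fs_target) return(env)

  # zero-phase FFT lowpass: flat to 0.8 * nyq_t, raised-cosine to nyq_t
  n <- length(env)
  m <- stats::nextn(n, c(2, 3, 5))
  nyq_t <- fs_target / 2
  f <- (seq_len(m) - 1) * fs_audio / m
  f <- pmin(f, fs_audio - f)                     # two-sided frequency axis
  gain <- rep(1, m)
  trans <- f > 0.8 * nyq_t & f < nyq_t
  gain[trans] <- 0.5 * (1 + cos(pi * (f[trans] - 0.8 * nyq_t) / (0.2 * nyq_t)))
  gain[f >= nyq_t] <- 0
  env_lp <- Re(fft(fft(c(env, numeric(m - n))) * gain,
                   inverse = TRUE) / m)[seq_len(n)]

  t_in <- (seq_len(n) - 1) / fs_audio
  t_out <- seq(0, (n - 1) / fs_audio, by = 1 / fs_target)
  pmax(0, approx(t_in, env_lp, xout = t_out)$y)
}

#' Narrowband instantaneous phase
#'
#' Zero-phase band-pass (4th-order Butterworth applied forward and backward
#' via `signal::filtfilt`) around `fc +/- halfwidth`, followed by the Hilbert
#' instantaneous phase. Phase is returned modulo 2*pi in (-pi, pi].
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param fc Band center frequency (Hz).
#' @param halfwidth Band half-width (Hz), default 0.5 (a 1 Hz band).
#' @return Phase sequence in radians, same length as `x`.
#' @export
narrowband_phase <- function(x, fs, fc, halfwidth = 0.5) {
  if (fc - halfwidth <= 0) {
    stop_invalid("band [%g, %g] Hz extends to or below 0 Hz",
                 fc - halfwidth, fc + halfwidth)
  }
  if (fc + halfwidth >= fs / 2) {
    stop_invalid("band edge %g Hz reaches Nyquist (%g Hz)",
                 fc + halfwidth, fs / 2)
  }
  bf <- signal::butter(2, c(fc - halfwidth, fc + halfwidth) / (fs / 2),
                       type = "pass")
  Arg(analytic_signal(signal::filtfilt(bf, x)))
}

#' Phase-locking value of two phase sequences
#'
#' `PLV = (1/T) | sum_t exp(i (theta1(t) - theta2(t))) |`: the modulus of
#' the time-averaged unit phasor of the phase difference. 0 means no
#' consistent phase relation, 1 perfect synchrony.
#'
#' @param theta1,theta2 Phase sequences in radians, equal length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(theta1, theta2) {
  if (length(theta1) != length(theta2)) {
    stop_invalid("phase sequences differ in length (%d vs %d)",
                 length(theta1), length(theta2))
  }
  if (length(theta1) < 2) stop_invalid("need at least 2 samples")
  Mod(mean(exp(1i * (theta1 - theta2))))
}

#' Frequency-scanned phase-locking value
#'
#' For each center frequency, band-pass both signals (`fc +/- halfwidth`),
#' take Hilbert phases, trim the filter's edge transients (`2/halfwidth`
#' seconds from each end), and compute the PLV of the pair. The default grid
#' spans 1.1-30 Hz in 0.3 Hz steps (97 center frequencies).
#'
#' @param source_wave Neural source waveform.
#' @param envelope Stimulus envelope at the same sampling rate.
#' @param fs Sampling rate (Hz).
#' @param fmin,fmax,step Center-frequency grid (Hz).
#' @param halfwidth Band half-width (Hz).
#' @return A `plv_spectrum`: data frame with `freq` and `plv`, plus
#'   attributes `halfwidth` and `fs`.
#' @export
plv_spectrum <- function(source_wave, envelope, fs,
                         fmin = 1.1, fmax = 30, step = 0.3, halfwidth = 0.5) {
  if (length(source_wave) != length(envelope)) {
    stop_invalid("source and envelope differ in length")
  }
  if (fmax + halfwidth >= fs / 2) {
    stop_invalid("fmax + halfwidth reaches Nyquist")
  }
  trim <- as.integer(round(2 / halfwidth * fs))
  n <- length(source_wave)
  if (n <= 2 * trim + 2) {
    stop_invalid("signals too short (%d samples) for %g s edge trimming",
                 n, 2 / halfwidth)
  }
  keep <- (trim + 1):(n - trim)
  freqs <- seq(fmin, fmax, by = step)
  vals <- vapply(freqs, function(fc) {
    th1 <- narrowband_phase(source_wave, fs, fc, halfwidth)[keep]
    th2 <- narrowband_phase(envelope, fs, fc, halfwidth)[keep]
    plv(th1, th2)
  }, numeric(1))
  out <- data.frame(freq = freqs, plv = vals)
  class(out) <- c("plv_spectrum", "data.frame")
  attr(out, "halfwidth") <- halfwidth
  attr(out, "fs") <- fs
  out
}

#' @export
plot.plv_spectrum <- function(x, ...) {
  graphics::plot(x$freq, x$plv, type = "l", xlab = "Frequency (Hz)",
                 ylab = "PLV", ylim = c(0, 1), ...)
  invisible(x)
}

#' Peak PLV near the nominal stimulus rate
#'
#' The entrainment magnitude for a condition: the maximum of the PLV
#' spectrum over center frequencies within `rate +/- window`. Ties resolve
#' to the lowest frequency.
#'
#' @param spectrum A `plv_spectrum`.
#' @param nominal_rate Stimulus presentation rate (Hz).
#' @param window Search half-window (Hz), default 0.5.
#' @return List with `peak_plv` and `peak_freq`.
#' @export
peak_plv <- function(spectrum, nominal_rate, window = 0.5) {
  sel <- spectrum$freq >= nominal_rate - window &
    spectrum$freq <= nominal_rate + window
  if (!any(sel)) {
    stop_invalid("no center frequency within %g +/- %g Hz", nominal_rate, window)
  }
  f <- spectrum$freq[sel]; v <- spectrum$plv[sel]
  i <- which.max(v)  # first maximum = lowest frequency on the ordered grid
  list(peak_plv = v[i], peak_freq = f[i])
}

#' Normalized cross-correlation between envelope and source waveform
#'
#' Control analysis: Pearson cross-correlation as a function of lag; returns
#' the maximum absolute correlation within `+/- max_lag` and its lag.
#' Positive lag means the source waveform follows the envelope (neural
#' response delayed relative to the stimulus). The absolute value is taken
#' because source polarity is sign-ambiguous.
#'
#' @param envelope Stimulus envelope.
#' @param source_wave Source waveform, same length and sampling rate.
#' @param fs Sampling rate (Hz).
#' @param max_lag Maximum lag in seconds (default 0.5).
#' @return List with `xcorr_max` (absolute correlation in \[0, 1\]) and
#'   `xcorr_lag` (seconds).
#' @export
crosscorr <- function(envelope, source_wave, fs, max_lag = 0.5) {
  if (length(envelope) != length(source_wave)) {
    stop_invalid("signals differ in length")
  }
  if (max_lag >= length(envelope) / fs / 2) {
    stop_invalid("max_lag must be below half the signal duration")
  }
  if (var(envelope) == 0 || var(source_wave) == 0) {
    stop_invalid("zero-variance input; cross-correlation undefined")
  }
  cc <- ccf(source_wave, envelope, lag.max = as.integer(round(max_lag * fs)),
            plot = FALSE, type = "correlation")
  i <- which.max(abs(cc$acf))
  # ccf(x, y) at lag k correlates x[t + k] with y[t]: k > 0 means the
  # source leads shifted forward, i.e. the source follows the envelope by k.
  list(xcorr_max = abs(cc$acf[i]), xcorr_lag = cc$lag[i] / fs)
}
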