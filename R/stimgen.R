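#' Synthesize a click token
#'
#' A rectangular positive pulse of 100 microseconds (at least one sample),
#' unit peak amplitude. Clicks are the broadband non-speech token of the
#' rate/jitter designs.
#'
#' @param fs Sampling rate in Hz.
#' @return A `token_waveform` object: list with `samples`, `fs`, `kind`,
#'   `duration` (seconds).
#' @examples
#' tok <- synthesize_click(48818)
#' length(tok$samples)  # 5 samples = round(100e-6 * 48818)
#' @export
synthesize_click <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_invalid("`fs` must be a positive number, got %s", format(fs))
  }
  n <- max(1L, as.integer(round(100e-6 * fs)))
  structure(
    list(samples = rep(1, n), fs = fs, kind = "click", duration = n / fs),
    class = "token_waveform"
  )
}

#' Synthesize a 60 ms consonant-vowel syllable token
#'
#' Source-filter approximation of a /ba/-like token: a brief low-amplitude
#' noise burst (the plosive release) followed by a voiced segment — a glottal
#' pulse train filtered through a cascade of formant resonators with a rising
#' first-formant transition. The waveform is edge-ramped and peak-normalized.
#' Deterministic given `seed`.
#'
#' @param fs Sampling rate in Hz (>= 8000; must exceed twice the highest
#'   formant).
#' @param f0 Voice fundamental in Hz, in \[80, 300\].
#' @param formants Steady-state formant frequencies in Hz (default F1-F3 of
#'   an adult male /a/-like vowel).
#' @param seed Integer seed for the burst noise.
#' @return A `token_waveform` of 60 ms duration.
#' @export
synthesize_syllable <- function(fs, f0 = 120, formants = c(700, 1220, 2600),
                                seed = 1L) {
  if (!is.numeric(fs) || length(fs) != 1 || fs < 8000) {
    stop_invalid("`fs` must be >= 8000 Hz for syllable synthesis")
  }
  if (f0 < 80 || f0 > 300) stop_invalid("`f0` must lie in [80, 300] Hz")
  if (max(formants) * 2 >= fs) {
    stop_invalid("fs = %g too low to represent formant at %g Hz",
                 fs, max(formants))
  }
  n <- as.integer(round(0.060 * fs))
  tt <- (seq_len(n) - 1) / fs

  with_seed(seed, function() {
    # glottal source: impulse train at f0, slight spectral tilt
    src <- numeric(n)
    src[1 + as.integer(round(seq(0, 0.060, by = 1 / f0) * fs))[
      seq(0, 0.060, by = 1 / f0) * fs < n - 1]] <- 1
    src <- stats::filter(src, 0.94, method = "recursive")  # -6 dB/oct tilt
    src <- as.numeric(src)
    # plosive burst: 5 ms of noise at token onset, low amplitude
    nb <- as.integer(round(0.005 * fs))
    burst <- numeric(n)
    burst[seq_len(nb)] <- rnorm(nb) * 0.15 * seq(1, 0, length.out = nb)
    # voicing ramps on after the burst
    voice_gain <- pmin(1, pmax(0, (tt - 0.004) / 0.012))
    x <- src * voice_gain + burst

    # time-varying formant cascade: F1 rises 300 -> formants[1] over 30 ms
    f1_track <- formants[1] - (formants[1] - 300) *
      pmax(0, 1 - tt / 0.030)
    bw <- c(90, 110, 170)
    for (k in seq_along(formants)) {
      fk <- if (k == 1) f1_track else rep(formants[k], n)
      r <- exp(-pi * bw[k] / fs)
      theta <- 2 * pi * fk / fs
      y <- numeric(n); y1 <- 0; y2 <- 0
      for (i in seq_len(n)) {
        a1 <- 2 * r * cos(theta[i]); a2 <- -r * r
        y[i] <- (1 - r) * x[i] + a1 * y1 + a2 * y2
        y2 <- y1; y1 <- y[i]
      }
      x <- y
    }

    # 5 ms raised-cosine edge ramps, peak normalization
    nr <- as.integer(round(0.005 * fs))
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
    x <- x / max(abs(x)) * 0.95
    structure(
      list(samples = x, fs = fs, kind = "syllable", duration = n / fs),
      class = "token_waveform"
    )
  })
}

#' Specification of a token train
#'
#' @param rate Nominal token presentation rate in Hz (tokens per second).
#' @param jitter Periodicity jitter as a fraction in \[0, 1): the uniformly
#'   jittered half-ISI spans `ISI/2 * (1 +/- jitter)`.
#' @param n_tokens Number of tokens in the train.
#' @param fs Audio sampling rate in Hz.
#' @param seed Integer seed for the ISI draws.
#' @return A `train_spec` object.
#' @export
train_spec <- function(rate, jitter = 0, n_tokens = 1000, fs = 48818,
                       seed = 1L) {
  if (rate <= 0) stop_invalid("`rate` must be positive")
  if (jitter < 0 || jitter >= 1) {
    stop_invalid("`jitter` must lie in [0, 1): %g would allow non-positive ISIs",
                 jitter)
  }
  if (n_tokens < 1) stop_invalid("`n_tokens` must be >= 1")
  structure(
    list(rate = rate, jitter = jitter, n_tokens = as.integer(n_tokens),
         fs = fs, seed = as.integer(seed)),
    class = "train_spec"
  )
}

#' Draw interstimulus intervals for a jittered train
#'
#' Each onset-to-onset ISI is the sum of a fixed half-period and a uniformly
#' jittered half-period: `ISI = ISI_nom/2 + U(ISI_nom/2 (1 - jitter),
#' ISI_nom/2 (1 + jitter))`, so the expected ISI equals `1/rate` at every
#' jitter level and only the degree of periodicity varies. At `jitter = 0`
#' every ISI equals the nominal period exactly.
#'
#' @param spec A [train_spec()].
#' @return Numeric vector of `n_tokens - 1` intervals in seconds.
#' @export
draw_isis <- function(spec) {
  stopifnot(inherits(spec, "train_spec"))
  isi <- 1 / spec$rate
  m <- spec$n_tokens - 1L
  if (m == 0L) return(numeric(0))
  if (spec$jitter == 0) return(rep(isi, m))
  with_seed(spec$seed, function() {
    isi / 2 + runif(m, isi / 2 * (1 - spec$jitter), isi / 2 * (1 + spec$jitter))
  })
}

#' Build a stimulus train from a token and a train specification
#'
#' Places copies of the token at onsets derived from [draw_isis()], first
#' onset at time 0. Errors if the token outlasts the smallest possible ISI
#' (tokens may never overlap).
#'
#' @param token A `token_waveform`.
#' @param spec A `train_spec` with the same sampling rate as the token.
#' @return A `stimulus_train`: list with `onsets` (s), `isis` (s), `audio`,
#'   `fs`, `spec`.
#' @export
build_train <- function(token, spec) {
  stopifnot(inherits(token, "token_waveform"), inherits(spec, "train_spec"))
  if (token$fs != spec$fs) {
    stop_invalid("token fs (%g) != spec fs (%g)", token$fs, spec$fs)
  }
  isis <- draw_isis(spec)
  if (length(isis) && token$duration >= min(isis)) {
    k <- which.min(isis)
    stop_invalid(
      "token duration %.4f s overlaps ISI #%d (%.4f s); reduce duration or jitter",
      token$duration, k, min(isis))
  }
  onsets <- c(0, cumsum(isis))
  ntok <- length(token$samples)
  n <- as.integer(round((onsets[length(onsets)] + 1 / spec$rate) * spec$fs))
  n <- max(n, as.integer(round(onsets[length(onsets)] * spec$fs)) + ntok)
  audio <- numeric(n)
  idx0 <- as.integer(round(onsets * spec$fs))
  for (i in seq_along(idx0)) {
    j <- idx0[i] + seq_len(ntok)
    audio[j] <- audio[j] + token$samples
  }
  structure(
    list(onsets = onsets, isis = isis, audio = audio, fs = spec$fs,
         spec = spec, kind = token$kind),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf(
    "<stimulus_train> %s, rate %.1f Hz, jitter %.0f%%, %d tokens, %.1f s @ %g Hz\n",
    x$kind, x$spec$rate, 100 * x$spec$jitter, length(x$onsets),
    length(x$audio) / x$fs, x$fs))
  invisible(x)
}

#' Equate a set of trains in RMS amplitude
#'
#' Rescales every train so its audio RMS matches the first train's
#' (relative scaling only; no absolute calibration is applied).
#'
#' @param trains List of `stimulus_train` objects.
#' @return The list with rescaled audio.
#' @export
rms_equalize <- function(trains) {
  if (!length(trains)) stop_invalid("need at least one train")
  rms <- vapply(trains, function(tr) sqrt(mean(tr$audio^2)), numeric(1))
  if (any(rms == 0)) {
    stop_invalid("train %d is silent (RMS 0); cannot equalize",
                 which(rms == 0)[1])
  }
  ref <- rms[1]
  lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    tr$audio <- tr$audio * (ref / rms[i])
    tr
  })
}

#' Acoustic diagnostics of a stimulus train
#'
#' Computes the ISI distribution, the normalized autocorrelation function
#' (ACF) of the Hilbert envelope, the lag of the first post-zero-lag ACF
#' maximum, and the envelope magnitude spectrum with the energy at the
#' nominal rate. The ACF is computed on the envelope (not the raw bipolar
#' waveform) so click and syllable trains are comparable; the first-peak
#' search starts at half the nominal period to skip the lag-0 main lobe.
#'
#' @param train A `stimulus_train`.
#' @param max_lag Maximum ACF lag in seconds.
#' @param fs_env Envelope sampling rate for the diagnostics (Hz); the
#'   envelope is computed with [stimulus_envelope()].
#' @return An `acoustic_diagnostics` object: `isi_mean`, `isi_hist`, `acf`
#'   (data frame lag/value), `acf_first_peak_lag` (s), `spectrum` (data
#'   frame freq/magnitude), `f0_energy`.
#' @export
diagnostics <- function(train, max_lag = 1, fs_env = 500) {
  stopifnot(inherits(train, "stimulus_train"))
  if (max_lag <= 0) stop_invalid("`max_lag` must be positive")
  dur <- length(train$audio) / train$fs
  if (dur <= 2 * max_lag) {
    stop_invalid("train duration %.2f s must exceed 2 * max_lag = %.2f s",
                 dur, 2 * max_lag)
  }
  env <- stimulus_envelope(train$audio, train$fs, fs_env)
  lag_max <- as.integer(round(max_lag * fs_env))
  ac <- as.numeric(acf(env, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)
  lags <- (seq_along(ac) - 1) / fs_env

  isi_nom <- 1 / train$spec$rate
  first <- which(lags > isi_nom / 2)[1]
  peak_lag <- NA_real_
  if (!is.na(first)) {
    # a genuine period peak must dominate a +/-20 ms neighbourhood and rise
    # above the (demeaned) baseline; bare sample-to-sample maxima would pick
    # up residual resampling ripple
    k <- max(1L, as.integer(round(0.020 * fs_env)))
    for (i in max(first, k + 1):(length(ac) - k)) {
      nb <- ac[(i - k):(i + k)]
      if (ac[i] > 0 && ac[i] == max(nb) && ac[i] > ac[i - 1]) {
        peak_lag <- lags[i]
        break
      }
    }
  }

  spec_env <- env - mean(env)
  m <- stats::nextn(length(spec_env), c(2, 3, 5))
  mag <- Mod(fft(c(spec_env, numeric(m - length(spec_env)))))[
    seq_len(floor(m / 2))]
  freqs <- (seq_along(mag) - 1) * fs_env / m
  # energy at the nominal rate, Welch-style: a single full-length
  # periodogram bin is exponentially noisy for aperiodic trains, so average
  # the magnitude at the rate bin over up-to-8 segments
  n_seg <- max(1L, min(8L, floor(length(spec_env) / (20 * fs_env))))
  seg_len <- floor(length(spec_env) / n_seg)
  f0_energy <- mean(vapply(seq_len(n_seg), function(s) {
    seg <- spec_env[((s - 1) * seg_len + 1):(s * seg_len)]
    ms <- stats::nextn(seg_len, c(2, 3, 5))
    magf <- Mod(fft(c(seg, numeric(ms - seg_len))))[seq_len(floor(ms / 2))]
    fr <- (seq_along(magf) - 1) * fs_env / ms
    magf[which.min(abs(fr - train$spec$rate))]
  }, numeric(1)))

  structure(
    list(
      isi_mean = if (length(train$isis)) mean(train$isis) else NA_real_,
      isi_hist = if (length(train$isis)) {
        graphics::hist(train$isis, breaks = 20, plot = FALSE)
      } else NULL,
      acf = data.frame(lag = lags, value = ac),
      acf_first_peak_lag = peak_lag,
      spectrum = data.frame(freq = freqs, magnitude = mag),
      f0_energy = f0_energy
    ),
    class = "acoustic_diagnostics"
  )
}
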