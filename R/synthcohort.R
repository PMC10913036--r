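#' Expected phase-locking value of a von Mises phase-noise process
#'
#' A neural oscillation whose phase deviates from the stimulus phase by von
#' Mises(0, kappa) noise has mean resultant length — hence expected PLV —
#' equal to the Bessel ratio `I1(kappa) / I0(kappa)`. This is the analytic
#' oracle for parameter-recovery checks.
#'
#' @param kappa Concentration parameter(s), >= 0.
#' @return Expected PLV in \[0, 1).
#' @export
expected_plv <- function(kappa) {
  if (any(kappa < 0)) stop_invalid("`kappa` must be non-negative")
  # scaled Bessel ratio up to ~1e4; beyond that besselI underflows even
  # scaled, so switch to the large-kappa asymptotic series
  ifelse(kappa == 0, 0,
         ifelse(kappa <= 1e4,
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE),
                1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3)))
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler, mean direction 0.
#'
#' @param n Number of draws.
#' @param kappa Concentration >= 0 (0 gives the circular uniform).
#' @return Angles in (-pi, pi\].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop_invalid("`kappa` must be non-negative")
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Pink (1/f) noise
#'
#' FFT-shaped Gaussian noise with power spectral density proportional to
#' 1/f (amplitude ~ f^-1/2), normalized to unit standard deviation. Used as
#' the ongoing-EEG background of synthetic source activity.
#'
#' @param n Number of samples.
#' @return Numeric vector, sd 1.
#' @export
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(m))
  k <- c(1, seq_len(m - 1))              # DC shares the first bin's weight
  w <- 1 / sqrt(pmin(k, m - k + 1))
  x <- Re(fft(X * w, inverse = TRUE) / m)[seq_len(n)]
  x / sd(x)
}

#' Generative specification of a synthetic subject-condition
#'
#' @param kappa von Mises concentration of the neural phase around the
#'   stimulus envelope phase (>= 0). Expected PLV is [expected_plv()].
#' @param snr_db Oscillation-to-background power ratio in dB.
#' @param evoked_kernel Optional impulse-response (numeric vector at the EEG
#'   sampling rate) convolved with the token-onset impulses; adds harmonic
#'   structure at integer multiples of the rate.
#' @param osc_freq Oscillation frequency in Hz; `NULL` means the train's
#'   nominal rate.
#' @param noise_tau Correlation (block) duration of the phase-noise process
#'   in seconds. Must exceed the analysis filter's integration time
#'   (~1/halfwidth) for the programmed concentration to be the measured
#'   quantity; default 3 s.
#' @return An `entrainment_spec` object.
#' @export
entrainment_spec <- function(kappa, snr_db = 30, evoked_kernel = NULL,
                             osc_freq = NULL, noise_tau = 3) {
  if (kappa < 0) stop_invalid("`kappa` must be non-negative")
  if (noise_tau <= 0) stop_invalid("`noise_tau` must be positive")
  structure(
    list(kappa = kappa, snr_db = snr_db, evoked_kernel = evoked_kernel,
         osc_freq = osc_freq, noise_tau = noise_tau),
    class = "entrainment_spec"
  )
}

#' Canonical auditory evoked-response kernel
#'
#' A P1-N1-P2-like impulse response (positive deflection near 50 ms,
#' dominant negativity near 100 ms, positivity near 180 ms), 400 ms long.
#' Convolving it with token onsets adds phase-locked energy at the
#' presentation rate and its integer harmonics.
#'
#' @param fs Sampling rate (Hz), default 500.
#' @param gain Peak amplitude scale (nAm).
#' @return Numeric kernel.
#' @export
auditory_evoked_kernel <- function(fs = 500, gain = 1) {
  tt <- seq(0, 0.4, by = 1 / fs)
  g <- function(mu, sig) exp(-(tt - mu)^2 / (2 * sig^2))
  k <- 0.5 * g(0.05, 0.015) - 1.0 * g(0.10, 0.020) + 0.6 * g(0.18, 0.030)
  gain * k / max(abs(k))
}

#' Generate bilateral auditory-cortex source activity locked to a train
#'
#' Each hemisphere's source current is
#' `A cos(phi_stim(t) + eps(t)) + kernel (x) onsets + pink noise`, where
#' `phi_stim` is the narrowband Hilbert phase of the train envelope at the
#' oscillation frequency and `eps` is a piecewise-constant von Mises(0,
#' kappa) phase-noise process (independent per hemisphere, one draw per
#' `noise_tau` block). The oscillation amplitude `A` is set from `snr_db`
#' relative to the unit-variance background.
#'
#' @param train A `stimulus_train`.
#' @param spec An `entrainment_spec`.
#' @param duration Seconds of activity to generate (must fit in the train).
#' @param fs EEG sampling rate (Hz), default 500.
#' @param seed Integer seed.
#' @param envelope Optional precomputed stimulus envelope at `fs` (else
#'   derived from the train's audio).
#' @return A `source_waveforms` with 2 rows (AC-left/right tangential), in
#'   nominal nAm.
#' @export
generate_source_activity <- function(train, spec, duration, fs = 500,
                                     seed = NULL, envelope = NULL) {
  stopifnot(inherits(train, "stimulus_train"),
            inherits(spec, "entrainment_spec"))
  train_dur <- length(train$audio) / train$fs
  if (duration > train_dur + 1e-9) {
    stop_invalid("duration %.2f s exceeds train duration %.2f s",
                 duration, train_dur)
  }
  n <- as.integer(round(duration * fs))
  osc_freq <- if (is.null(spec$osc_freq)) train$spec$rate else spec$osc_freq

  env <- if (is.null(envelope)) {
    stimulus_envelope(train$audio, train$fs, fs)
  } else envelope
  phi <- narrowband_phase(env[seq_len(min(length(env), n + fs))], fs, osc_freq)
  phi <- phi[seq_len(n)]

  evoked <- numeric(n)
  if (!is.null(spec$evoked_kernel)) {
    imp <- numeric(n)
    idx <- 1L + as.integer(round(train$onsets * fs))
    idx <- idx[idx >= 1 & idx <= n]
    imp[idx] <- 1
    ev <- signal::conv(imp, spec$evoked_kernel)
    evoked <- ev[seq_len(n)]
  }

  A <- sqrt(2) * 10^(spec$snr_db / 20)        # background has unit variance
  blk <- as.integer(round(spec$noise_tau * fs))
  nblk <- ceiling(n / blk)

  with_seed(seed, function() {
    currents <- matrix(0, 2, n)
    for (h in 1:2) {
      eps <- rep(rvonmises(nblk, spec$kappa), each = blk)[seq_len(n)]
      currents[h, ] <- A * cos(phi + eps) + evoked + pink_noise(n)
    }
    structure(
      list(currents = currents,
           labels = c("AC-left-tangential", "AC-right-tangential")),
      class = "source_waveforms"
    )
  })
}

# ---- fixture montage ------------------------------------------------------

#' Standard 64-channel 10-10 label set
#'
#' @return Character vector of 64 channel names.
#' @export
default_channel_names <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz")
}

# Approximate planar 10-10 coordinates (x: left negative; y: anterior
# positive) parsed from the label. Accuracy is irrelevant for the synthetic
# leadfield; only smoothness and left-right symmetry matter.
channel_positions <- function(names = default_channel_names()) {
  rows <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
            TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -4.8)
  pos <- t(vapply(names, function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z]+)(z|[0-9]+)$", nm))[[1]]
    band <- m[2]; suf <- m[3]
    y <- rows[[band]]
    if (suf == "z") return(c(0, y))
    d <- as.integer(suf)
    x <- ceiling(d / 2) * if (d %% 2 == 1) -1 else 1
    c(x, y)
  }, numeric(2)))
  colnames(pos) <- c("x", "y")
  pos
}

# Permutation mapping each channel to its left-right mirror.
mirror_permutation <- function(names = default_channel_names()) {
  mirror_name <- vapply(names, function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z]+)(z|[0-9]+)$", nm))[[1]]
    if (m[3] == "z") return(nm)
    d <- as.integer(m[3])
    paste0(m[2], if (d %% 2 == 1) d + 1 else d - 1)
  }, character(1))
  match(mirror_name, names)
}

#' Fixture leadfield montage for bilateral auditory-cortex sources
#'
#' Builds a spatially smooth 64 x 2 leadfield with dipolar (tangential)
#' topographies over the left and right temporal sites, exactly mirrored
#' under the left-right channel permutation. Columns are zero-mean
#' (consistent with common-average-referenced data). A seeded smooth
#' perturbation (symmetric in the mirror sense) makes distinct but
#' reproducible fixtures. Stands in for a dipole-model leadfield when real
#' ones are unavailable; real leadfields can be supplied to
#' [source_montage()] instead.
#'
#' @param n_channels Number of channels (currently 64, the 10-10 set).
#' @param seed Integer seed for the perturbation.
#' @return A `source_montage` with condition number below 1e3.
#' @export
make_fixture_montage <- function(n_channels = 64, seed = 1L) {
  names <- default_channel_names()
  if (n_channels != length(names)) {
    stop_invalid("fixture montage supports %d channels (10-10 set)",
                 length(names))
  }
  if (n_channels < 2) stop_invalid("need at least as many channels as sources")
  pos <- channel_positions(names)
  perm <- mirror_permutation(names)

  # tangential dipole over left AC (near T7): anterior-posterior derivative
  # of a Gaussian centered at (-4, 0)
  d2 <- (pos[, "x"] + 4)^2 + pos[, "y"]^2
  left <- (pos[, "y"] + 0.6) * exp(-d2 / (2 * 1.8^2))

  pert <- with_seed(seed, function() {
    a <- rnorm(3, sd = 0.05)
    a[1] * cos(0.7 * pos[, "y"]) + a[2] * cos(0.5 * abs(pos[, "x"])) +
      a[3] * sin(0.4 * pos[, "y"]) * exp(-abs(pos[, "x"]) / 3)
  })
  left <- left * (1 + pert)
  right <- left[perm]                 # exact mirror by construction
  L <- cbind(left - mean(left), right - mean(right))
  L <- L / max(abs(L)) * 5            # ~5 uV per nAm, plausible scale
  colnames(L) <- NULL

  m <- source_montage(L, names, c("AC-left-tangential", "AC-right-tangential"))
  if (cond_number(L) >= 1e3) {
    stop_invalid("fixture leadfield unexpectedly ill-conditioned")
  }
  m
}

cond_number <- function(L) {
  s <- svd(L)$d
  s[1] / s[length(s)]
}

#' Project source currents to the scalp
#'
#' Forward model: `EEG = L x sources`, plus white sensor noise at the given
#' signal-to-noise ratio, then common-average referencing (the reference
#' used throughout the pipeline).
#'
#' @param sources A `source_waveforms` or sources x samples matrix.
#' @param montage A `source_montage`; column count must match the sources.
#' @param sensor_noise_db Sensor SNR in dB (signal RMS over noise RMS);
#'   `Inf` (default) adds no noise.
#' @param seed Integer seed for the noise.
#' @return Channels x samples matrix (microvolts), common-average
#'   referenced, with `rownames` set to the montage channel names.
#' @export
project_to_scalp <- function(sources, montage, sensor_noise_db = Inf,
                             seed = NULL) {
  stopifnot(inherits(montage, "source_montage"))
  S <- if (inherits(sources, "source_waveforms")) sources$currents
       else as.matrix(sources)
  if (nrow(S) != ncol(montage$leadfield)) {
    stop_invalid("%d source rows but montage has %d sources",
                 nrow(S), ncol(montage$leadfield))
  }
  eeg <- montage$leadfield %*% S
  if (is.finite(sensor_noise_db)) {
    sig_rms <- sqrt(mean(eeg^2))
    noise_sd <- sig_rms * 10^(-sensor_noise_db / 20)
    eeg <- eeg + with_seed(seed, function() {
      matrix(rnorm(length(eeg), sd = noise_sd), nrow(eeg), ncol(eeg))
    })
  }
  eeg <- rereference_common_average(eeg)
  rownames(eeg) <- montage$channel_names
  eeg
}
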