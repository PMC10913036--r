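#' The deduplicated rate x jitter condition design
#'
#' Two stimulus domains (click, syllable) crossed with five presentation
#' rates at 0% jitter plus five jitter levels at the 4.5 Hz rate; the
#' duplicated (rate 4.5, jitter 0) cell is counted once per stimulus, giving
#' 18 distinct conditions. Each cell carries the generator's default phase
#' locking concentration (`kappa`), the ground truth for that condition.
#'
#' @param rates Presentation rates in Hz.
#' @param jitters Jitter fractions applied at `jitter_rate`.
#' @param jitter_rate Rate carrying the periodicity manipulation (Hz).
#' @return Data frame with columns `stimulus`, `rate`, `jitter`, `kappa`.
#' @export
design_conditions <- function(rates = c(2.1, 3.3, 4.5, 8.5, 14.9),
                              jitters = c(0, 0.2, 0.4, 0.6, 0.8),
                              jitter_rate = 4.5) {
  grid <- rbind(
    expand.grid(stimulus = c("click", "syllable"), rate = rates, jitter = 0,
                stringsAsFactors = FALSE),
    expand.grid(stimulus = c("click", "syllable"), rate = jitter_rate,
                jitter = jitters, stringsAsFactors = FALSE)
  )
  grid <- unique(grid)
  grid <- grid[order(grid$stimulus, grid$jitter, grid$rate), ]
  rownames(grid) <- NULL
  grid$kappa <- mapply(default_kappa, grid$stimulus, grid$rate, grid$jitter)
  grid
}

#' Default ground-truth phase-locking concentration per condition
#'
#' The synthetic cohort's study conditions. Syllable locking peaks at the
#' 4.5 Hz syllabic rate and declines approximately linearly in expected PLV
#' across jitter (kappa 4, 2.8, 2, 1.2, 0.7 for 0-80%); click locking is
#' invariant to jitter (kappa 2) and rises mildly toward fast rates.
#'
#' @param stimulus `"click"` or `"syllable"`.
#' @param rate Presentation rate (Hz).
#' @param jitter Jitter fraction.
#' @return Scalar kappa.
#' @export
default_kappa <- function(stimulus, rate, jitter = 0) {
  rates <- c(2.1, 3.3, 4.5, 8.5, 14.9)
  jits <- c(0, 0.2, 0.4, 0.6, 0.8)
  if (jitter > 0) {
    j <- which.min(abs(jits - jitter))
    if (stimulus == "syllable") return(c(4, 2.8, 2, 1.2, 0.7)[j])
    return(2)
  }
  r <- which.min(abs(rates - rate))
  if (stimulus == "syllable") return(c(2, 3, 4, 2.5, 1.5)[r])
  c(2, 2, 2, 2.5, 3)[r]
}

#' Configuration for a synthetic entrainment experiment
#'
#' @param n_subjects Cohort size (default 24).
#' @param conditions Condition data frame as from [design_conditions()]
#'   (columns `stimulus`, `rate`, `jitter`, `kappa`; optional `snr_db`).
#' @param snr_db Oscillation SNR in dB for all conditions lacking their own.
#' @param sensor_noise_db Scalp sensor SNR in dB (`Inf` = noiseless).
#' @param fs EEG sampling rate (Hz).
#' @param audio_fs Stimulus audio sampling rate (Hz).
#' @param n_tokens Tokens per train; `NULL` derives the count from the
#'   record duration.
#' @param seg_start,seg_len Analysis segment offset and length (s).
#' @param fmin,fmax,step,halfwidth PLV band-scan grid (Hz).
#' @param window Peak-search half-window around the nominal rate (Hz).
#' @param max_lag Cross-correlation lag bound (s).
#' @param seed Master seed; per-(subject, condition) seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 24, conditions = design_conditions(),
                       snr_db = 30, sensor_noise_db = 20, fs = 500,
                       audio_fs = 48818, n_tokens = NULL,
                       seg_start = 1, seg_len = 30,
                       fmin = 1.1, fmax = 30, step = 0.3, halfwidth = 0.5,
                       window = 0.5, max_lag = 0.5, seed = 1L) {
  if (!all(c("stimulus", "rate", "jitter", "kappa") %in% names(conditions))) {
    stop_invalid("`conditions` needs columns stimulus, rate, jitter, kappa")
  }
  structure(
    list(n_subjects = n_subjects, conditions = conditions, snr_db = snr_db,
         sensor_noise_db = sensor_noise_db, fs = fs, audio_fs = audio_fs,
         n_tokens = n_tokens, seg_start = seg_start, seg_len = seg_len,
         fmin = fmin, fmax = fmax, step = step, halfwidth = halfwidth,
         window = window, max_lag = max_lag, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Reduced configuration for fast runs
#'
#' Four subjects, the jitter arm of the design only, coarse audio rate and
#' a narrow band scan around the stimulated rate. Intended for quick checks
#' and examples.
#'
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
ci_profile <- function(...) {
  cond <- design_conditions()
  cond <- cond[cond$rate == 4.5 & cond$stimulus == "syllable", ]
  defaults <- list(n_subjects = 4, conditions = cond, audio_fs = 8000,
                   fmin = 3.5, fmax = 5.6)
  args <- utils::modifyList(defaults, list(...))
  do.call(run_config, args)
}

#' Analyze one condition recording
#'
#' Scalp EEG -> common-average reference -> montage inversion -> 30 s
#' segment -> band-scanned PLV against the stimulus envelope -> peak
#' extraction near the nominal rate, plus the cross-correlation control.
#' One result row per source.
#'
#' @param eeg Channels x samples matrix (microvolts).
#' @param montage A `source_montage`.
#' @param train The `stimulus_train` that drove the recording.
#' @param fs EEG sampling rate (Hz).
#' @param envelope Optional precomputed envelope at `fs` (else derived from
#'   the train).
#' @param seg_start,seg_len Analysis segment (s).
#' @param fmin,fmax,step,halfwidth Band-scan grid (Hz).
#' @param window Peak-search half-window (Hz).
#' @param max_lag Cross-correlation lag bound (s).
#' @return Data frame, one row per source: `source`, `peak_plv`,
#'   `peak_freq`, `xcorr_max`, `xcorr_lag`.
#' @export
analyze_condition <- function(eeg, montage, train, fs = 500, envelope = NULL,
                              seg_start = 1, seg_len = 30,
                              fmin = 1.1, fmax = 30, step = 0.3,
                              halfwidth = 0.5, window = 0.5, max_lag = 0.5) {
  eeg <- rereference_common_average(eeg)
  swf <- apply_montage(eeg, montage)
  swf <- extract_segment(swf, fs, seg_start, seg_len)
  if (is.null(envelope)) {
    envelope <- stimulus_envelope(train$audio, train$fs, fs)
  }
  env_seg <- extract_segment(envelope, fs, seg_start, seg_len)
  rows <- lapply(seq_len(nrow(swf$currents)), function(h) {
    src <- swf$currents[h, ]
    spec <- plv_spectrum(src, env_seg, fs, fmin = fmin, fmax = fmax,
                         step = step, halfwidth = halfwidth)
    pk <- peak_plv(spec, train$spec$rate, window)
    xc <- crosscorr(env_seg, src, fs, max_lag)
    data.frame(source = swf$labels[h], peak_plv = pk$peak_plv,
               peak_freq = pk$peak_freq, xcorr_max = xc$xcorr_max,
               xcorr_lag = xc$xcorr_lag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average results over hemispheres
#'
#' Collapses left/right source rows to one row per subject x condition by
#' averaging the outcome measures (peak extraction precedes collapsing).
#'
#' @param results Per-source results from [run_experiment()].
#' @return Aggregated data frame without the `source` column.
#' @export
collapse_hemispheres <- function(results) {
  keys <- intersect(c("subject_id", "stimulus", "rate", "jitter", "kappa"),
                    names(results))
  vals <- intersect(c("peak_plv", "peak_freq", "xcorr_max", "xcorr_lag"),
                    names(results))
  stats::aggregate(results[vals], results[keys], mean)
}

synthesize_token <- function(kind, fs) {
  if (kind == "click") synthesize_click(fs) else synthesize_syllable(fs)
}

#' Run a seeded synthetic entrainment experiment end to end
#'
#' For every subject and condition: builds the token train, generates
#' phase-locked bilateral source activity, projects it to the scalp with
#' sensor noise, inverts the montage, and measures peak PLV and the
#' cross-correlation control. Fully deterministic given the config seed;
#' per-(subject, condition) seeds are derived additively so enlarging the
#' cohort never changes existing subjects.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `results.csv` (one row per subject x condition x source),
#'   `summary.json` and `manifest.json`. Refuses to overwrite an existing
#'   results directory unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a directory holding previous results.
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, a list with `results` (data frame), `summary` (list),
#'   `manifest` (list).
#' @export
run_experiment <- function(config, out_dir = NULL, overwrite = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) {
    if (file.exists(file.path(out_dir, "results.csv")) && !overwrite) {
      stop_invalid(
        "'%s' already holds results; pass overwrite = TRUE to replace them",
        out_dir)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  cond <- config$conditions
  duration <- config$seg_start + config$seg_len + 1
  montage <- make_fixture_montage(seed = config$seed)
  tokens <- lapply(stats::setNames(nm = unique(cond$stimulus)),
                   synthesize_token, fs = config$audio_fs)

  all_rows <- list()
  for (j in seq_len(nrow(cond))) {
    cj <- cond[j, ]
    snr <- if ("snr_db" %in% names(cond)) cj$snr_db else config$snr_db
    espec <- entrainment_spec(kappa = cj$kappa, snr_db = snr)
    # worst-case ISI is ISI * (1 - jitter/2); size the train so even a
    # maximally shortened draw still covers the analysis window
    n_tok <- if (is.null(config$n_tokens)) {
      as.integer(ceiling(cj$rate * duration / (1 - cj$jitter / 2))) + 2L
    } else config$n_tokens
    if (verbose) {
      message(sprintf("condition %d/%d: %s %.1f Hz, jitter %.0f%%",
                      j, nrow(cond), cj$stimulus, cj$rate, 100 * cj$jitter))
    }
    for (i in seq_len(config$n_subjects)) {
      seed_train <- derive_seed(config$seed, i, 2L * j)
      seed_src <- derive_seed(config$seed, i, 2L * j + 1L)
      tspec <- train_spec(cj$rate, cj$jitter, n_tok, config$audio_fs,
                          seed = seed_train)
      train <- build_train(tokens[[cj$stimulus]], tspec)
      env <- stimulus_envelope(train$audio, train$fs, config$fs)
      src <- generate_source_activity(train, espec, duration, config$fs,
                                      seed = seed_src, envelope = env)
      eeg <- project_to_scalp(src, montage, config$sensor_noise_db,
                              seed = seed_src + 1L)
      res <- analyze_condition(
        eeg, montage, train, config$fs, envelope = env,
        seg_start = config$seg_start, seg_len = config$seg_len,
        fmin = config$fmin, fmax = config$fmax, step = config$step,
        halfwidth = config$halfwidth, window = config$window,
        max_lag = config$max_lag)
      res <- cbind(
        data.frame(subject_id = sprintf("S%02d", i), stimulus = cj$stimulus,
                   rate = cj$rate, jitter = cj$jitter, kappa = cj$kappa,
                   stringsAsFactors = FALSE),
        res)
      all_rows[[length(all_rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL

  collapsed <- collapse_hemispheres(results)
  cell_means <- stats::aggregate(
    collapsed[c("peak_plv", "xcorr_max")],
    collapsed[c("stimulus", "rate", "jitter", "kappa")], mean)
  cell_means$expected_plv <- expected_plv(cell_means$kappa)

  summary <- list(conditions = cell_means)
  for (stim in unique(collapsed$stimulus)) {
    sub <- collapsed[collapsed$stimulus == stim, ]
    jitter_rates <- unique(sub$rate[sub$jitter > 0])
    if (length(jitter_rates) == 1 && config$n_subjects >= 3) {
      sub <- sub[sub$rate == jitter_rates, ]
      if (length(unique(sub$jitter)) >= 3) {
        tr <- linear_trend(sub)
        summary[[paste0("jitter_trend_", stim)]] <-
          tr[c("estimate", "slope_per_step", "t", "df", "p")]
      }
    }
  }

  manifest <- list(
    package = "oscillotrack",
    seed = config$seed,
    n_subjects = config$n_subjects,
    fs = config$fs, audio_fs = config$audio_fs,
    seg_start = config$seg_start, seg_len = config$seg_len,
    analysis = config[c("fmin", "fmax", "step", "halfwidth", "window",
                        "max_lag")],
    sensor_noise_db = config$sensor_noise_db,
    conditions = cond
  )

  if (!is.null(out_dir)) {
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(results = results, summary = summary, manifest = manifest))
}

#' Parameter-recovery experiment: pooled PLV versus the Bessel-ratio oracle
#'
#' Simulates a cohort locked to a periodic 4.5 Hz click train at each
#' requested concentration, runs every record through the scalp projection
#' and montage inversion, and estimates the condition PLV by pooling the
#' in-band phase differences (source minus envelope, edge-trimmed) across
#' all records and hemispheres before taking the resultant modulus. Pooling
#' matters: a single band-limited 30 s record carries only ~20 independent
#' phase-noise draws, so per-record PLV is upward-biased at low kappa,
#' whereas the pooled resultant is a consistent estimate of
#' `I1(kappa)/I0(kappa)`.
#'
#' @param kappas Concentrations to recover.
#' @param n_subjects Records per concentration (default 24).
#' @param snr_db Oscillation SNR (dB).
#' @param sensor_noise_db Scalp sensor SNR (dB).
#' @param duration Record duration (s), default 30.
#' @param rate Stimulation rate (Hz).
#' @param fs EEG sampling rate (Hz).
#' @param audio_fs Audio sampling rate for the click train (Hz).
#' @param halfwidth Analysis band half-width (Hz).
#' @param seed Master seed.
#' @return Data frame with `kappa`, `expected`, `measured`, `n_records`.
#' @export
recovery_experiment <- function(kappas = c(0.5, 1, 2, 4, 8), n_subjects = 24,
                                snr_db = 30, sensor_noise_db = 20,
                                duration = 30, rate = 4.5, fs = 500,
                                audio_fs = 8000, halfwidth = 0.5, seed = 1L) {
  n_tok <- as.integer(ceiling(rate * (duration + 2))) + 1L
  tspec <- train_spec(rate, 0, n_tok, audio_fs, seed = seed)
  train <- build_train(synthesize_click(audio_fs), tspec)
  env <- stimulus_envelope(train$audio, train$fs, fs)
  montage <- make_fixture_montage(seed = seed)

  n <- as.integer(round(duration * fs))
  trim <- as.integer(round(2 / halfwidth * fs))
  keep <- (trim + 1):(n - trim)
  th_env <- narrowband_phase(env[seq_len(n)], fs, rate, halfwidth)[keep]

  rows <- lapply(seq_along(kappas), function(k) {
    espec <- entrainment_spec(kappa = kappas[k], snr_db = snr_db)
    dphi <- unlist(lapply(seq_len(n_subjects), function(i) {
      s <- derive_seed(seed, i, k)
      src <- generate_source_activity(train, espec, duration, fs,
                                      seed = s, envelope = env)
      eeg <- project_to_scalp(src, montage, sensor_noise_db, seed = s + 1L)
      rec <- apply_montage(eeg, montage)
      lapply(1:2, function(h) {
        narrowband_phase(rec$currents[h, ], fs, rate, halfwidth)[keep] - th_env
      })
    }))
    data.frame(kappa = kappas[k], expected = expected_plv(kappas[k]),
               measured = Mod(mean(exp(1i * dphi))),
               n_records = 2L * n_subjects)
  })
  do.call(rbind, rows)
}
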