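# oscillotrack

Cortico-acoustic entrainment analysis for rhythmic auditory streams.

When the brain listens to a rhythmic stream of sounds, ongoing neural
activity in auditory cortex phase-locks to the temporal envelope of the
stimulus. `oscillotrack` implements the full measurement chain for this
phenomenon and a ground-truth simulator to validate it:

* **Stimulus generation** — trains of 100 µs clicks or 60 ms synthetic
  consonant–vowel syllables at parametric rates (2.1–14.9 Hz) and
  interstimulus-interval jitters (0–80% of the half-period, drawn
  uniformly so the mean rate is preserved), with acoustic diagnostics
  (ISI distribution, envelope autocorrelation, envelope spectrum).
* **Synthetic EEG cohort** — bilateral auditory-cortex source currents
  with von Mises phase noise of known concentration κ around the stimulus
  envelope phase, optional evoked-response kernels, pink background
  noise, and projection through a 64-channel leadfield with sensor noise.
* **Source analysis** — common-average referencing and linear montage
  inversion (SWF = pinv(L) × EEG) reducing scalp data to left/right
  auditory-cortex source waveforms.
* **Entrainment measurement** — the band-scanned phase-locking value

  PLV = (1/T) · | Σₜ exp(i·[θ₁(t) − θ₂(t)]) |

  between the Hilbert phases of the stimulus envelope and the source
  waveforms, evaluated in 1 Hz bands at center frequencies 1.1–30 Hz
  (0.3 Hz steps), with the condition magnitude taken as the spectrum peak
  within ±0.5 Hz of the nominal rate; plus a normalized cross-correlation
  control.
* **Group statistics** — square-root transform, within-subject
  orthogonal-polynomial linear trend across jitter, paired
  stimulus-domain contrasts with Holm adjustment, Pearson correlation.

The generative model is self-validating: a source whose phase carries von
Mises(0, κ) noise has expected PLV equal to the Bessel ratio
I₁(κ)/I₀(κ), so the pipeline's output can be checked against an analytic
oracle (`expected_plv()`, `recovery_experiment()`).

## Worked example

Simulate one subject listening to a 20%-jittered 4.5 Hz click train whose
neural locking concentration is κ = 4, then recover the entrainment:

```r
library(oscillotrack)

tok   <- synthesize_click(8000)
spec  <- train_spec(rate = 4.5, jitter = 0.2, n_tokens = 160,
                    fs = 8000, seed = 42)
train <- build_train(tok, spec)
train
#> <stimulus_train> click, rate 4.5 Hz, jitter 20%, 160 tokens, 35.8 s @ 8000 Hz
mean(train$isis) * 1000          # jitter preserves the 222.2 ms mean ISI
#> 223.7

gt      <- entrainment_spec(kappa = 4, snr_db = 30)
expected_plv(4)                  # ground truth the pipeline should see
#> [1] 0.8635519
montage <- make_fixture_montage(seed = 1)
env     <- stimulus_envelope(train$audio, train$fs, 500)
src     <- generate_source_activity(train, gt, duration = 32,
                                    seed = 42, envelope = env)
eeg     <- project_to_scalp(src, montage, sensor_noise_db = 20, seed = 43)

analyze_condition(eeg, montage, train, envelope = env,
                  fmin = 3.5, fmax = 5.6)
#>                source peak_plv peak_freq xcorr_max xcorr_lag
#> 1  AC-left-tangential    0.907       4.4     0.213     0.216
#> 2 AC-right-tangential    0.864       4.4     0.199     0.004
```

Both hemispheres lock near the programmed 0.864 (single 30 s records read
slightly high at strong locking; see the methods vignette for the
estimator's bias analysis and the pooled estimator used for exact
parameter recovery). The peak sits at 4.4 Hz, the scanned band nearest
the 4.5 Hz stimulation rate.

Cohort-scale runs go through `run_experiment()`:

```r
cfg <- ci_profile(n_subjects = 24, seed = 11)   # syllable trains, 5 jitters
out <- run_experiment(cfg, out_dir = "results/jitter-run")
```

which writes a tidy `results.csv` (one row per subject × condition ×
hemisphere), a `summary.json` with per-condition mean peak PLV, the
ground-truth expected PLV, and the within-subject jitter trend, and a
`manifest.json` with every seed needed to reproduce the run.

## Documentation

See the methods vignette (`vignettes/entrainment-methods.Rmd`) for the
generative model, parameter meanings and defaults, numerical choices, and
what synthetic validation does and does not establish about real EEG.
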