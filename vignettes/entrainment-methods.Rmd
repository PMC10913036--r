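---
title: "Measuring cortico-acoustic entrainment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cortico-acoustic entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillotrack)
```

## The scientific problem

When a listener hears a rhythmic stream of sounds — clicks, or repeated
syllables — ongoing neural activity in auditory cortex aligns its phase to
the temporal structure of the stream. `oscillotrack` quantifies this
*cortico-acoustic entrainment* with the phase-locking value (PLV) between
the Hilbert phase of the stimulus amplitude envelope and the phase of
auditory-cortex source waveforms derived from scalp EEG, scanned across
narrow frequency bands. Because no public recordings accompany this kind of
passive-listening paradigm, the package also ships a fully parametric
synthetic cohort: every stage of the analysis can be validated against
known ground truth before it ever touches real data.

## Stimulus model

A condition is a train of identical tokens — a 100 µs rectangular click or
a 60 ms synthetic consonant–vowel syllable — presented at a nominal rate
$r$ (2.1, 3.3, 4.5, 8.5 or 14.9 Hz in the standard design). Periodicity is
degraded by *jitter*: each onset-to-onset interval is

$$\mathrm{ISI} = \frac{1}{2r} + U\!\left[\frac{1-j}{2r},\ \frac{1+j}{2r}\right],$$

the sum of a fixed half-period and a uniformly jittered half-period with
jitter fraction $j \in \{0, 0.2, 0.4, 0.6, 0.8\}$. This construction keeps
the *expected* rate exactly $r$ at every jitter level, so only the degree
of periodicity varies; at $j = 0$ every interval equals $1/r$ exactly
(222 ms at 4.5 Hz). ISIs are defined onset-to-onset: with a fixed token
duration that is the only convention under which the mean rate is
preserved. The full design — five rates per stimulus domain at 0% jitter
plus five jitter levels at 4.5 Hz, with the duplicated (4.5 Hz, 0%) cell
counted once — has 18 distinct conditions (`design_conditions()`).

The syllable is re-synthesized by a source–filter model (glottal impulse
train, three-formant cascade with a rising F1 transition, 5 ms burst and
edge ramps): only its 60 ms duration and broadband spectrum are
constrained, not the spectral detail of any particular recorded token.
Audio defaults to 48,818 Hz sampling; diagnostics operate on a 500 Hz
envelope. Trains intended for presentation are RMS-equated
(`rms_equalize()`); absolute calibration (dB SPL) is hardware territory
and is never applied to samples.

Acoustic diagnostics (`diagnostics()`) summarize a train by its ISI
distribution, the autocorrelation function (ACF) of its Hilbert envelope
(computed on the envelope, not the bipolar waveform, so clicks and
syllables are comparable; lag 0 normalized to 1), and the envelope
spectrum. The first ACF maximum past half the nominal period marks the
train's dominant periodicity; a genuine peak must dominate a ±20 ms
neighbourhood so residual resampling ripple is not mistaken for structure.
The energy at the nominal rate is read Welch-style — the rate bin averaged
over up to eight ~30 s segments — because a single full-length periodogram
bin is exponentially noisy for aperiodic trains.

## Synthetic cohort: the generative model

Each synthetic subject-condition produces bilateral auditory-cortex source
currents

$$s_h(t) = A\cos\!\big(\varphi_{\mathrm{stim}}(t) + \varepsilon_h(t)\big)
  + (k \ast o)(t) + \eta_h(t),$$

where $\varphi_{\mathrm{stim}}$ is the narrowband Hilbert phase of the
stimulus envelope at the presentation rate, $\varepsilon_h$ is a
piecewise-constant von Mises$(0, \kappa)$ phase-noise process (independent
per hemisphere), $k \ast o$ is an optional P1–N1–P2-like evoked kernel
convolved with token onsets (adding harmonics at $2F_0, 3F_0, \dots$), and
$\eta_h$ is pink ($1/f$) background noise emulating the EEG spectrum. The
oscillation amplitude $A$ is set from the oscillation-to-background SNR in
dB. The controlled quantity is the concentration $\kappa$: the expected
PLV of such a process is the Bessel ratio

$$\mathbb{E}[\mathrm{PLV}] = \frac{I_1(\kappa)}{I_0(\kappa)},$$

implemented as `expected_plv()` and used as the analytic recovery oracle
throughout the test suite. The von Mises draws use a Best–Fisher rejection
sampler written for the package.

**Phase-noise timescale.** The phase noise is piecewise constant in blocks
of `noise_tau` seconds, default 3 s. The block duration is a genuine
modelling constraint, not a free dial: the ±0.5 Hz analysis filter
integrates over roughly $1/\text{halfwidth} = 2$ s, and any phase noise
faster than that is partially averaged *inside* the filter, which inflates
measured PLV far above $I_1(\kappa)/I_0(\kappa)$ (simulations show ~0.90
measured at $\kappa = 2$, expected 0.70, when noise varies per token at
4.5 Hz). Blocks of 3 s are the shortest timescale that survives the filter
essentially intact while still providing several independent phase draws
per 30 s record.

**Consequence: per-record PLV is biased at low κ.** A 30 s record
band-limited to 1 Hz holds only about $T \cdot B \approx 20$ independent
phase-noise draws. The PLV is the modulus of a mean phasor, and the
modulus of a noisy resultant is biased upward — at $\kappa = 0.5$
(true PLV 0.24) a single record reads ~0.3–0.5 regardless of how the noise
is generated. This is a property of the estimator under time–bandwidth
limits, not an implementation defect. The package therefore separates two
uses:

* *condition summaries* use the per-subject, per-condition **peak PLV**
  (maximum over the scan window, hemispheres averaged after peak
  extraction), matching standard practice; these are fine for
  within-design comparisons because the bias is shared across cells;
* *parameter recovery* (`recovery_experiment()`) pools the in-band phase
  differences across all records and hemispheres of a cohort *before*
  taking the modulus, which is a consistent estimator of the Bessel ratio.
  With 96 records per concentration the pooled estimate carries a standard
  error near 0.01–0.02 and lands within ±0.05 of
  $I_1(\kappa)/I_0(\kappa)$ across $\kappa \in \{0.5, 1, 2, 4, 8\}$.

**Scalp model.** A fixture leadfield (`make_fixture_montage()`) maps the
two tangential sources to 64 channels laid out on the 10-10 system:
spatially smooth dipolar topographies over the temporal sites, exactly
mirrored under the left–right channel permutation, zero-mean columns
(consistent with common-average referencing), condition number ~1. White
sensor noise is added at a configurable SNR (default 20 dB) and the data
are common-average referenced. This stands in for a dipole-model
leadfield; real leadfields can be supplied via `source_montage()`. The
four-shell conductor constants sometimes quoted for such models are
metadata only — no volume-conduction physics is simulated.

**Default ground truth.** The condition grid carries per-cell κ defaults
(`default_kappa()`), fixed once as the package's study conditions:
syllable locking peaks at the 4.5 Hz syllabic rate and declines
approximately linearly in expected PLV across jitter
(κ = 4, 2.8, 2, 1.2, 0.7 → expected PLV 0.86, 0.79, 0.70, 0.53, 0.33),
while click locking is jitter-invariant (κ = 2) and rises mildly toward
fast rates. These emulate the qualitative pattern reported for human
listeners — speech-like tokens entrain more strongly and lose entrainment
with aperiodicity, clicks do not — and give the group statistics a known
signal to detect. The default cohort size is 24 subjects.

## The analysis chain

1. **Envelope** (`stimulus_envelope()`): modulus of the FFT-based analytic
   signal of the audio, anti-alias low-passed below 250 Hz (zero-phase
   FFT-domain filter with a raised-cosine transition from 200 to 250 Hz)
   and linearly interpolated onto the 500 Hz EEG grid. An FFT filter is
   used instead of polyphase resampling because the 48,818→500 Hz ratio
   reduces to an impractically large rational factor; the FFT route is
   exactly zero-phase, which is what phase comparison requires. Residual
   ripple can dip marginally below zero and is clamped.
2. **Source waveforms** (`rereference_common_average()`,
   `apply_montage()`): EEG is common-average referenced and multiplied by
   the Moore–Penrose pseudoinverse of the leadfield — the linear-inverse
   reading of SWF = L⁻¹ × EEG, exact for square full-rank montages and
   least-squares for the tall 64 × 2 case. Only the tangential component
   per hemisphere is modelled, the orientation that captures most of the
   auditory evoked variance.
3. **Band scan** (`plv_spectrum()`): for each center frequency from 1.1 to
   30 Hz in 0.3 Hz steps (97 bands), both signals are band-passed
   (fc ± 0.5 Hz, 4th-order Butterworth run forward and backward via
   `filtfilt` — zero group delay is essential when phases are compared),
   Hilbert phases extracted, and the PLV
   $\tfrac{1}{T}\lvert\sum_t e^{i(\theta_1(t)-\theta_2(t))}\rvert$
   computed over one continuous 30 s segment per condition (not
   epoch-averaged across trials — the continuous-record reading of the
   method). Narrowband filters ring, so $2/\text{halfwidth} = 4$ s are
   trimmed from each end before the PLV.
4. **Peak extraction** (`peak_plv()`): the condition's entrainment
   magnitude is the spectrum maximum within ±0.5 Hz of the nominal rate;
   ties resolve to the lowest frequency. Hemispheres are averaged after
   peak extraction.
5. **Control** (`crosscorr()`): normalized cross-correlation between
   envelope and source waveform, maximum absolute value within ±500 ms
   (the lag bound is a package default; positive lag means the neural
   signal follows the stimulus). The absolute value is taken because
   source polarity is sign-ambiguous.

## Group statistics

The group layer deliberately replaces mixed-model ANOVA with exactly
testable within-subject machinery: a square-root transform
(`sqrt_transform()`), an orthogonal-polynomial linear contrast per subject
followed by a one-sample t-test (`linear_trend()`), paired t-tests for
stimulus-domain contrasts at single cells (`paired_contrast()`), Holm
step-down control across the five per-jitter contrasts
(`jitter_contrasts()`), and Pearson correlation (`correlate()`). All
p-values are two-sided at α = 0.05. A pooled-cell mixed model would give
different (much larger) degrees of freedom; published F/t statistics from
such models are therefore not comparable targets, and the per-subject
contrast df = N − 1 is reported instead. When within-subject variability
is exactly zero (deterministic fixtures), the t machinery degenerates; the
result is flagged `exact` with p forced to 0 or 1 rather than returning
`NaN`.

## Numerical choices and degenerate inputs

* FFTs are zero-padded to 2-3-5-smooth lengths (`nextn`); R's FFT
  degrades to near-quadratic cost on lengths with large prime factors.
* `filtfilt` with a 4th-order Butterworth at a 1 Hz bandwidth on 500 Hz
  data is numerically stable (checked: a pure tone's phase advances at the
  tone frequency to <1e-3 rad/sample after trimming).
* Zero-jitter trains are generated without consuming random numbers, so
  the periodic train is bit-identical across seeds.
* A token longer than the shortest drawn ISI raises an overlap error
  naming the offending interval; jitter ≥ 1 is rejected at construction
  (it would allow non-positive intervals).
* Silent trains cannot be RMS-equalized; zero-variance signals cannot be
  cross-correlated; both raise degenerate-input errors.
* Seeds: every stochastic stage takes an explicit seed and runs in a
  private RNG stream (the caller's `.Random.seed` is untouched).
  Experiment-level seeds derive per (subject, condition) additively, so
  enlarging a cohort never perturbs existing subjects' data.

## Problem sizes

The shipped experiment profiles are sized for interactive work: the
reduced profile (`ci_profile()`) runs 24 subjects × 5 jitter conditions at
8 kHz audio with a 3.5–5.6 Hz scan in ~1–2 minutes; the recovery check
pools 96 records per concentration (~1 minute); the full 18-condition,
97-band, 48,818 Hz configuration reproduces the complete design and is
correspondingly heavier. All sizes are ordinary function arguments.

## What the synthetic cohort does and does not show

The generator produces exactly the signal class the analysis assumes: a
narrowband oscillation phase-locked to the envelope, plus harmonically
structured evoked activity and 1/f background, passed through a linear,
instantaneous, well-conditioned forward model. Passing tests therefore
demonstrate that the pipeline measures what it claims to measure — that
PLV recovers programmed phase concentration, that jitter manipulations
propagate into measured declines, that the statistics detect programmed
trends. They do not demonstrate robustness to what real EEG adds: eye and
muscle artifact, non-stationarity, imperfect head models, inter-subject
anatomical variability, or neural nonlinearities beyond the additive
evoked kernel. The EDF input path (`read_edf()`, `match_channels()`)
exists for real recordings, but claims about real data require real data.

## Known limitations

* The 11-source regional montage used with commercial source analysis
  software is not reproduced; only the two auditory tangential sources are
  modelled, and the pseudoinverse of a 64 × 2 leadfield is an explicit
  simplification of proprietary regularized inversion.
* Per-record PLV at low true locking is upward-biased (see above); users
  comparing absolute PLV levels across studies should prefer the pooled
  estimator or treat single-record values as ordinal.
* The syllable token is an acoustic stand-in constrained only by duration
  and broad spectral shape.
* No time-resolved (sliding-window) PLV, wavelet phase estimation, or
  inter-trial coherence.
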