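# Shared fixtures, built in code at test time.

# Small periodic or jittered click train at a modest audio rate.
make_click_train <- function(rate = 4.5, jitter = 0, n_tokens = 150,
                             fs = 2000, seed = 3L) {
  build_train(synthesize_click(fs),
              train_spec(rate, jitter, n_tokens, fs, seed = seed))
}

# Phase sequences of a pure tone, the analytic workhorse of phase tests.
tone_phase <- function(freq, fs, dur) {
  2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs)
}

# Brute-force PLV: explicit loop over the unit phasors (independent oracle).
plv_bruteforce <- function(theta1, theta2) {
  acc <- 0 + 0i
  for (t in seq_along(theta1)) {
    acc <- acc + exp(1i * (theta1[t] - theta2[t]))
  }
  Mod(acc / length(theta1))
}
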