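test_that("expected PLV is the Bessel ratio, stable to extreme kappa", {
  expect_equal(expected_plv(0), 0)
  expect_equal(expected_plv(2), besselI(2, 1) / besselI(2, 0),
               tolerance = 1e-12)
  expect_equal(expected_plv(2), 0.6978, tolerance = 1e-4)
  expect_gte(expected_plv(1e6), 0.999999)
  expect_true(all(diff(expected_plv(c(0.5, 1, 2, 4, 8))) > 0))
  expect_error(expected_plv(-1), "non-negative")
})

test_that("von Mises sampler matches its analytic moments", {
  set.seed(12)
  for (kappa in c(0.5, 2, 8)) {
    x <- rvonmises(20000, kappa)
    expect_true(all(x >= -pi & x <= pi))
    # mean resultant length -> I1/I0(kappa); SE ~ 1/sqrt(2n)
    expect_lt(abs(Mod(mean(exp(1i * x))) - expected_plv(kappa)), 0.015)
    # symmetric about 0
    expect_lt(abs(mean(sin(x))), 0.02)
  }
  u <- rvonmises(5000, 0)
  expect_lt(Mod(mean(exp(1i * u))), 0.05)    # circular uniform
})

test_that("pink noise has unit sd and a falling spectrum", {
  set.seed(3)
  x <- pink_noise(2^14)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  p <- Mod(fft(x))^2
  lo <- mean(p[5:50]); hi <- mean(p[2000:4000])
  expect_gt(lo / hi, 10)                      # ~1/f: low >> high
})

test_that("source activity hits the perfect-locking and null limits", {
  tr <- make_click_train(rate = 4.5, n_tokens = 160, fs = 2000, seed = 2)
  env <- stimulus_envelope(tr$audio, tr$fs, 500)
  n <- 30 * 500
  keep <- 2001:(n - 2000)
  th_env <- narrowband_phase(env[1:n], 500, 4.5)[keep]

  # kappa -> Inf at high SNR: PLV ~ 1
  hi <- generate_source_activity(tr, entrainment_spec(1e6, snr_db = 40),
                                 30, seed = 5, envelope = env)
  th1 <- narrowband_phase(hi$currents[1, ], 500, 4.5)[keep]
  expect_gte(plv(th1, th_env), 0.99)

  # kappa = 0: PLV near the null floor (few independent phase blocks in
  # 30 s, so the floor is far above sqrt(pi/4T) for T samples; bound well
  # below any true locking instead)
  lo <- generate_source_activity(tr, entrainment_spec(0, snr_db = 40),
                                 30, seed = 5, envelope = env)
  th0 <- narrowband_phase(lo$currents[1, ], 500, 4.5)[keep]
  expect_lt(plv(th0, th_env), 0.45)

  # determinism and hemisphere independence
  again <- generate_source_activity(tr, entrainment_spec(0, snr_db = 40),
                                    30, seed = 5, envelope = env)
  expect_identical(lo$currents, again$currents)
  expect_false(identical(lo$currents[1, ], lo$currents[2, ]))

  expect_error(generate_source_activity(tr, entrainment_spec(2), 60),
               "duration")
})

test_that("an evoked kernel adds harmonic peaks above the baseline", {
  tr <- make_click_train(rate = 4.5, n_tokens = 160, fs = 2000, seed = 6)
  env <- stimulus_envelope(tr$audio, tr$fs, 500)
  spec <- entrainment_spec(kappa = 8, snr_db = 20,
                           evoked_kernel = auditory_evoked_kernel(500, 40))
  src <- generate_source_activity(tr, spec, 30, seed = 7, envelope = env)
  x <- src$currents[1, ]
  n <- length(x)
  p <- Mod(fft(x * signal::hanning(n)))^2
  fr <- (seq_len(n) - 1) * 500 / n
  band_pow <- function(f0) max(p[abs(fr - f0) < 0.2])
  # 2F0 and 3F0 peaks exceed the between-harmonic baseline
  expect_gt(band_pow(9), 5 * band_pow(6.75))
  expect_gt(band_pow(13.5), 5 * band_pow(11.25))
})

test_that("measured PLV increases with kappa on a coarse grid", {
  tr <- make_click_train(rate = 4.5, n_tokens = 160, fs = 2000, seed = 8)
  env <- stimulus_envelope(tr$audio, tr$fs, 500)
  n <- 30 * 500
  keep <- 2001:(n - 2000)
  th_env <- narrowband_phase(env[1:n], 500, 4.5)[keep]
  # pool 6 records per kappa to tame single-record bias/variance
  measured <- vapply(c(0.5, 2, 8), function(k) {
    d <- unlist(lapply(1:6, function(i) {
      src <- generate_source_activity(tr, entrainment_spec(k), 30,
                                      seed = 100L * i + round(10 * k),
                                      envelope = env)
      lapply(1:2, function(h) {
        narrowband_phase(src$currents[h, ], 500, 4.5)[keep] - th_env
      })
    }))
    Mod(mean(exp(1i * d)))
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})
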