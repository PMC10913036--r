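test_that("click token is a 100 us unit pulse with a one-sample floor", {
  expect_equal(length(synthesize_click(48818)$samples), 5)  # round(4.8818)
  expect_equal(length(synthesize_click(500)$samples), 1)
  expect_equal(length(synthesize_click(10000)$samples), 1)
  expect_equal(max(synthesize_click(48818)$samples), 1)
  expect_error(synthesize_click(0), "positive")
  expect_error(synthesize_click(-1), "positive")
})

test_that("syllable token: 60 ms, bounded, deterministic, guards formants", {
  syl <- synthesize_syllable(48818, f0 = 120)
  expect_equal(length(syl$samples), round(0.060 * 48818))
  expect_lte(max(abs(syl$samples)), 1)
  expect_equal(syl$duration, length(syl$samples) / 48818)
  syl2 <- synthesize_syllable(48818, f0 = 120)
  expect_identical(syl$samples, syl2$samples)
  syl3 <- synthesize_syllable(48818, f0 = 120, seed = 9L)
  expect_false(identical(syl$samples, syl3$samples))
  expect_error(synthesize_syllable(4000), ">= 8000")
  expect_error(synthesize_syllable(8000, formants = c(700, 1220, 4500)),
               "formant")
  expect_error(synthesize_syllable(48818, f0 = 50), "f0")
})

test_that("ISI draws have the stated uniform support and preserve the rate", {
  # jitter 0: every ISI exactly the nominal period
  isis0 <- draw_isis(train_spec(4.5, 0, 100, 2000))
  expect_true(all(isis0 == 1 / 4.5))
  expect_equal(var(isis0), 0)

  # jitter 0.8: support [ISI/2 * 1.2, ISI/2 * 1.8] + ISI/2, mean preserved
  isis <- draw_isis(train_spec(4.5, 0.8, 10000, 2000, seed = 7))
  isi <- 1 / 4.5
  expect_gte(min(isis), isi / 2 + isi / 2 * 0.2)
  expect_lte(max(isis), isi / 2 + isi / 2 * 1.8)
  expect_lt(abs(mean(isis) - isi), 0.01 * isi)

  # conservation of rate across jitters: |mean - 1/rate| < 3 SE
  for (j in c(0.2, 0.4, 0.6)) {
    isis_j <- draw_isis(train_spec(4.5, j, 5000, 2000, seed = 13))
    se <- (j * isi / 2) / sqrt(3) / sqrt(length(isis_j))
    expect_lt(abs(mean(isis_j) - isi), 3 * se + 1e-12)
  }

  expect_error(train_spec(4.5, 1.0, 10, 2000), "jitter")
  expect_error(train_spec(0, 0, 10, 2000), "rate")
})

test_that("trains place tokens at cumulative onsets without overlap", {
  tr <- make_click_train(rate = 2.1, jitter = 0, n_tokens = 1000)
  expect_equal(tr$onsets[1], 0)
  expect_true(all(diff(tr$onsets) > 0))
  expect_equal(length(tr$isis), length(tr$onsets) - 1)
  # 1000 tokens at 2.1 Hz: 999 periods ~ 475.7 s
  expect_equal(tr$onsets[1000], 999 / 2.1, tolerance = 1e-9)

  # zero jitter at an integer samples-per-period: exact periodicity
  tr2 <- make_click_train(rate = 2, jitter = 0, n_tokens = 50, fs = 500)
  period <- 500 / 2
  a <- tr2$audio
  expect_equal(a[seq_len(length(a) - period)],
               a[(period + 1):length(a)], tolerance = 0)

  # a token longer than the smallest ISI is an overlap error
  long_tok <- structure(list(samples = rep(1, 1500), fs = 2000,
                             kind = "click", duration = 0.75),
                        class = "token_waveform")
  expect_error(build_train(long_tok, train_spec(4.5, 0, 10, 2000)),
               "overlap")
})

test_that("rms equalization matches all trains to the first, scale-free", {
  t1 <- make_click_train(n_tokens = 50)
  t2 <- build_train(synthesize_syllable(8000),
                    train_spec(4.5, 0, 50, 8000, seed = 3))
  # resample-free comparison: equalize works per train, any fs
  eq <- rms_equalize(list(t1, t2))
  r <- vapply(eq, function(x) sqrt(mean(x$audio^2)), numeric(1))
  expect_equal(r[2] / r[1], 1, tolerance = 1e-9)

  one <- rms_equalize(list(t1))
  expect_identical(one[[1]]$audio, t1$audio)

  t2b <- t2; t2b$audio <- t2b$audio * 10
  eq2 <- rms_equalize(list(t1, t2b))
  expect_equal(eq2[[2]]$audio, eq[[2]]$audio, tolerance = 1e-12)

  silent <- t1; silent$audio <- silent$audio * 0
  expect_error(rms_equalize(list(silent)), "silent")
})

test_that("diagnostics recover the nominal period and its decay with jitter", {
  tr <- make_click_train(rate = 4.5, jitter = 0, n_tokens = 150)
  d <- diagnostics(tr, max_lag = 1)
  expect_equal(d$acf$value[1], 1)                 # lag-0 normalization
  expect_true(max(d$acf$value) == d$acf$value[1]) # lag 0 is the maximum
  expect_equal(d$acf_first_peak_lag * 1000, 222)  # nearest 2 ms bin to 1/4.5
  expect_true(all(d$spectrum$freq >= 0))
  # envelope-spectrum peak (above 1 Hz) sits at the bin nearest the rate
  above <- d$spectrum[d$spectrum$freq > 1 & d$spectrum$freq < 20, ]
  expect_equal(above$freq[which.max(above$magnitude)], 4.5, tolerance = 0.05)
  expect_error(diagnostics(tr, max_lag = 0), "max_lag")
})

test_that("energy at the nominal rate declines with jitter", {
  # averaged over a small seed family; single realizations touch the noise
  # floor at high jitter
  tok <- synthesize_click(4000)
  e <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(j) {
    mean(sapply(1:4, function(s) {
      tr <- build_train(tok, train_spec(4.5, j, 1000, 4000, seed = s))
      diagnostics(tr, max_lag = 0.5)$f0_energy
    }))
  })
  expect_true(all(diff(e) <= 0))
})
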