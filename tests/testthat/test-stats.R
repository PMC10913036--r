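make_cohort <- function(n_sub, jitters = c(0, 0.2, 0.4, 0.6, 0.8),
                        fn = function(s, j) 0.5) {
  do.call(rbind, lapply(seq_len(n_sub), function(s) {
    data.frame(subject_id = sprintf("S%02d", s), stimulus = "syllable",
               rate = 4.5, jitter = jitters,
               peak_plv = vapply(jitters, function(j) fn(s, j), numeric(1)))
  }))
}

test_that("square-root transform is exact and monotone", {
  expect_equal(sqrt_transform(c(0, 1, 0.25)), c(0, 1, 0.5))
  x <- runif(50)
  expect_equal(order(sqrt_transform(x)), order(x))
  expect_error(sqrt_transform(c(0.1, -0.2)), "negative")
})

test_that("linear trend detects deterministic declines and nulls", {
  dec <- make_cohort(8, fn = function(s, j) 0.8 - 0.5 * j)
  tr <- linear_trend(dec)
  expect_lt(tr$estimate, 0)
  expect_true(tr$exact)               # zero residual: flagged certainty
  expect_equal(tr$p, 0)
  expect_equal(tr$slope_per_step, -0.1, tolerance = 1e-9)

  # noisy decline is still detected
  set.seed(2)
  noisy <- make_cohort(10, fn = function(s, j) 0.8 - 0.5 * j + rnorm(1, 0, 0.05))
  trn <- linear_trend(noisy)
  expect_lt(trn$estimate, 0)
  expect_lt(trn$p, 0.05)

  # constant data: t = 0, p = 1
  const <- make_cohort(6, fn = function(s, j) 0.4)
  trc <- linear_trend(const)
  expect_equal(trc$t, 0)
  expect_equal(trc$p, 1)

  # unbalanced design names the hole
  expect_error(linear_trend(dec[-1, ]), "unbalanced")
  expect_error(linear_trend(dec[dec$jitter < 0.3, ]), "levels")
})

test_that("trend p-values are uniform under permuted labels", {
  set.seed(33)
  ps <- replicate(300, {
    tab <- make_cohort(8, fn = function(s, j) rnorm(1, 0.5, 0.1))
    linear_trend(tab)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trend power exceeds 0.9 for the programmed decline at N = 24", {
  # 0.02 PLV per jitter step against 0.01 between-subject contrast noise
  set.seed(44)
  hits <- mean(replicate(500, {
    tab <- make_cohort(24, fn = function(s, j) {
      0.7 - 0.02 * (j / 0.2) + rnorm(1, 0, 0.01)
    })
    tr <- linear_trend(tab)
    tr$p < 0.05 && tr$estimate < 0
  }))
  expect_gt(hits, 0.9)
})

test_that("paired contrasts handle identity, separation and real effects", {
  base <- make_cohort(8, fn = function(s, j) 0.5)
  both <- rbind(base, transform(base, stimulus = "click"))
  ct <- paired_contrast(both, at = list(jitter = 0))
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p, 1)

  shifted <- transform(base, stimulus = "click", peak_plv = peak_plv - 0.1)
  ct2 <- paired_contrast(rbind(base, shifted), at = list(jitter = 0.2))
  expect_true(ct2$exact)              # zero-noise separation is degenerate
  expect_equal(ct2$p, 0)
  expect_equal(ct2$estimate, 0.1)     # syllable - click, alphabetical

  expect_error(paired_contrast(base, at = list(jitter = 0)), "2 levels")
  holey <- shifted[!(shifted$subject_id == "S01" & shifted$jitter == 0.2), ]
  expect_error(paired_contrast(rbind(base, holey), at = list(jitter = 0.2)),
               "pairs")
})

test_that("paired contrast keeps nominal type-I error under the null", {
  set.seed(55)
  rej <- mean(replicate(1000, {
    a <- rnorm(12, 0.5, 0.05); b <- rnorm(12, 0.5, 0.05)
    tab <- data.frame(
      subject_id = rep(sprintf("S%02d", 1:12), 2),
      stimulus = rep(c("click", "syllable"), each = 12),
      jitter = 0, peak_plv = c(a, b))
    paired_contrast(tab, at = list(jitter = 0))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("syllable > click contrast is detected when programmed", {
  # per-subject paired difference of 0.15 with 0.05 noise, 200 replicates
  set.seed(66)
  hits <- mean(replicate(200, {
    n <- 12
    click <- rnorm(n, 0.55, 0.05)
    syl <- rnorm(n, 0.70, 0.05)
    tab <- data.frame(
      subject_id = rep(sprintf("S%02d", 1:n), 2),
      stimulus = rep(c("click", "syllable"), each = n),
      jitter = 0, peak_plv = c(click, syl))
    ct <- paired_contrast(tab, at = list(jitter = 0))
    ct$p < 0.05 && ct$estimate > 0
  }))
  expect_gte(hits, 0.95)
})

test_that("correlation matches affine cases and recovers rho", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -2 * x + 3)$r, -1)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(x, x[-1]), "length")

  set.seed(77)
  rho <- 0.65
  rs <- replicate(1000, {
    x <- rnorm(24)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(24)
    correlate(x, y)$r
  })
  expect_equal(mean(rs), rho, tolerance = 0.03)
})

test_that("per-jitter contrasts carry Holm-adjusted p-values", {
  set.seed(88)
  n <- 10
  tab <- do.call(rbind, lapply(c("click", "syllable"), function(st) {
    make_cohort(n, fn = function(s, j) {
      0.6 + (st == "syllable") * (0.2 - 0.2 * j) + rnorm(1, 0, 0.04)
    }) |> transform(stimulus = st)
  }))
  jc <- jitter_contrasts(tab)
  expect_equal(nrow(jc), 5)
  expect_true(all(jc$p_adj >= jc$p))
  expect_equal(jc$p_adj, p.adjust(jc$p, "holm"))
})
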