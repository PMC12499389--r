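test_that("censored autocovariance matches brute-force pair enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    x <- rnorm(n)
    valid <- runif(n) > 0.3
    if (sum(valid) < 2) valid[1:2] <- TRUE
    tr <- runif(1, 0.5, 3)
    max_lag <- sample(2:(n - 1), 1)
    acv <- censored_autocovariance(frame_series(x, tr, valid), max_lag)
    oracle <- brute_force_acv(x, valid, tr, max_lag)
    expect_lt(max(abs(acv$adjusted - oracle$adjusted)), 1e-12)
    expect_equal(acv$n_pairs, oracle$n_pairs)
  }
})

test_that("zero-lag value is the biased sample variance over valid frames", {
  set.seed(1)
  x <- rnorm(80)
  valid <- runif(80) > 0.2
  acv <- censored_autocovariance(frame_series(x, 2, valid), 10)
  xv <- x[valid] - mean(x[valid])
  expect_equal(acv$adjusted[1], sum(xv^2) / length(xv), tolerance = 1e-12)
  expect_equal(acv$q[1], 0)
})

test_that("an all-valid mask reproduces the unmasked estimator bit-for-bit", {
  set.seed(2)
  x <- rnorm(60)
  a1 <- censored_autocovariance(frame_series(x, 1.97), 30)
  a2 <- censored_autocovariance(frame_series(x, 1.97, rep(TRUE, 60)), 30)
  expect_identical(a1, a2)
  # and matches the ordinary biased-pair autocovariance before tapering
  xd <- x - mean(x)
  for (m in c(1, 5, 17)) {
    expect_equal(a1$raw_sum[m] / a1$n_pairs[m],
                 sum(xd[1:(60 - m + 1)] * xd[m:60]) / (60 - m + 1),
                 tolerance = 1e-12)
  }
})

test_that("autocovariance input validation", {
  expect_error(censored_autocovariance(
    frame_series(rnorm(10), 1, c(TRUE, rep(FALSE, 9)))), "valid frames")
  expect_error(censored_autocovariance(frame_series(rnorm(10), 1), 10),
               "max_lag")
  expect_error(frame_series(rnorm(5), -1), "tr")
  expect_error(frame_series(rnorm(5), 1, c(TRUE, FALSE)), "length")
})

test_that("cosine-transform PSD agrees with a direct DFT oracle", {
  set.seed(3)
  ts <- frame_series(rnorm(120), 1.97, runif(120) > 0.1)
  acv <- censored_autocovariance(ts)
  ps <- psd_via_cosine_transform(acv)
  oracle <- direct_dft_psd(acv$adjusted, 1.97, ps$freq)
  oracle <- pmax(oracle, 1e-12 * max(abs(oracle)))
  expect_lt(max(abs(ps$power - oracle)), 1e-10)
  expect_equal(ps$freq[1], 0)
  expect_equal(ps$freq[length(ps$freq)], 1 / (2 * 1.97))
  expect_true(all(diff(ps$freq) > 0))
})

test_that("a delta autocovariance yields a flat spectrum", {
  acv <- data.frame(lag = 1:30, q = (0:29) * 1.97 / 30, raw_sum = 0,
                    n_pairs = 100, adjusted = c(1, rep(0, 29)),
                    empty = FALSE)
  attr(acv, "tr") <- 1.97
  ps <- psd_via_cosine_transform(acv)
  expect_lt(diff(range(ps$power)), 1e-12)
})

test_that("a cosine autocovariance peaks at the matching grid frequency", {
  tr <- 1.97
  f0 <- 0.05
  lag <- 1:57
  acv <- data.frame(lag = lag, q = (lag - 1) * tr / 30, raw_sum = 0,
                    n_pairs = 100,
                    adjusted = cos(2 * pi * f0 * (lag - 1) * tr),
                    empty = FALSE)
  attr(acv, "tr") <- tr
  ps <- psd_via_cosine_transform(acv)
  expect_equal(ps$freq[which.max(ps$power)],
               ps$freq[which.min(abs(ps$freq - f0))], tolerance = 1e-12)
  expect_error(psd_via_cosine_transform(acv[0, ]), "empty")
})

test_that("exact semilog spectra give exact slopes; flat gives zero", {
  for (s in c(5, 10, 20)) {
    ps <- make_spectrum(function(f) 10^(2 - s * f))
    fit <- fit_spectral_slope(ps)
    expect_equal(fit$ss, s, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
  flat <- make_spectrum(function(f) rep(7, length(f)))
  expect_equal(fit_spectral_slope(flat)$ss, 0, tolerance = 1e-12)
})

test_that("slope of the analytic AR(1) spectrum matches an lm oracle", {
  ps <- make_spectrum(function(f) ar1_psd(0.9, 1.97, f))
  fit <- fit_spectral_slope(ps)
  idx <- ps$freq >= 0.015 & ps$freq <= 0.145
  ofit <- lm(log10(ps$power[idx]) ~ ps$freq[idx])
  expect_equal(fit$ss, -unname(coef(ofit)[2]), tolerance = 1e-9)
  expect_equal(fit$r2, summary(ofit)$r.squared, tolerance = 1e-9)
})

test_that("slope is invariant to amplitude scaling of the series", {
  set.seed(4)
  x <- rnorm(150)
  ssx <- function(v) {
    fit_spectral_slope(psd_via_cosine_transform(
      censored_autocovariance(frame_series(v, 1.97))))$ss
  }
  expect_equal(ssx(x), ssx(3 * x), tolerance = 1e-9)
  expect_equal(ssx(x), ssx(0.01 * x), tolerance = 1e-9)
})

test_that("too-coarse grids are rejected with the resolution named", {
  ps <- make_spectrum(function(f) 10^(2 - f), n_freq = 8)
  expect_error(fit_spectral_slope(ps), "grid resolution")
})

test_that("semilog vs log-log model comparison behaves on exact data", {
  semi <- make_spectrum(function(f) 10^(3 - 12 * f))
  cs <- compare_spectral_models(semi)
  expect_equal(cs$r2_semilog, 1, tolerance = 1e-9)
  expect_gt(cs$r2_semilog, cs$r2_loglog)
  pl <- make_spectrum(function(f) ifelse(f > 0, f^-1.2, 1))
  cp <- compare_spectral_models(pl)
  expect_equal(cp$r2_loglog, 1, tolerance = 1e-9)
  expect_gt(cp$r2_loglog, cp$r2_semilog)
})

test_that("subject maps: constant across identical parcels, scale-free", {
  set.seed(5)
  x <- rnorm(261)
  series <- list(`1` = frame_series(x, 1.97),
                 `2` = frame_series(x, 1.97),
                 `3` = frame_series(3 * x, 1.97))
  m <- subject_ss_map(series)
  expect_equal(m$ss[1], m$ss[2], tolerance = 1e-12)
  expect_equal(m$ss[1], m$ss[3], tolerance = 1e-9)

  geo <- data.frame(parcel_id = 1:3, medial_wall = c(FALSE, FALSE, TRUE))
  m2 <- subject_ss_map(series, geometry = geo)
  expect_identical(m2$parcel_id, c("1", "2"))
})

test_that("per-parcel failures carry the parcel id", {
  series <- list(ok = frame_series(rnorm(100), 1.97),
                 bad = frame_series(rnorm(100), 1.97,
                                    c(TRUE, rep(FALSE, 99))))
  expect_error(subject_ss_map(series), "bad")
})
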