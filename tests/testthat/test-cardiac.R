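tone <- function(f, dur = 10, fs = 250) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  uniform_series(tt, sin(2 * pi * f * tt), sampling_rate = fs)
}

test_that("ECG preprocessing passes the QRS band and rejects DC and mains", {
  dc <- uniform_series((0:2499) / 250, rep(1, 2500), sampling_rate = 250)
  expect_lt(max(abs(preprocess_ecg(dc)$value)), 1e-6)

  mid <- 500:2000
  expect_gt(max(abs(preprocess_ecg(tone(10))$value[mid])), 0.95)
  expect_lt(max(abs(preprocess_ecg(tone(60))$value[mid])), 0.05)

  out <- preprocess_ecg(tone(10))
  expect_identical(out$time, tone(10)$time)
  expect_error(
    preprocess_ecg(uniform_series((0:99) / 50, rnorm(100), sampling_rate = 50)),
    "sampling rate"
  )
})

test_that("R-peak detection errors on flat input and handles two beats", {
  flat <- uniform_series((0:999) / 250, rep(0, 1000), sampling_rate = 250)
  expect_error(detect_rpeaks(flat), "insufficient beats")

  two <- gen_ecg(c(0.5, 1.5), fs = 250)
  ibi <- detect_rpeaks(preprocess_ecg(two))
  expect_equal(nrow(ibi), 1)
  expect_equal(ibi$value, 1.0, tolerance = 1 / 250)
})

test_that("Poincare descriptors equal their closed-form oracles", {
  expect_error(poincare(ibi_series(c(0, 1, 2))), "at least 3")

  const <- ibi_series(cumsum(c(0, rep(1, 5))))
  pc <- poincare(const)
  expect_equal(pc$sd1, 0)
  expect_equal(pc$sd2, 0)

  rr <- c(0.8, 1.2, 0.8, 1.2, 0.8)
  ibi <- ibi_series(cumsum(c(0, rr)))
  pc2 <- poincare(ibi)
  # oracle: direct variance formulas computed here, not via the package
  vd <- var(diff(rr))
  vr <- var(rr)
  expect_equal(pc2$sd1, sqrt(vd / 2), tolerance = 1e-12)
  # the alternating record drives the closed form negative; it clamps at 0
  expect_equal(pc2$sd2, sqrt(max(2 * vr - vd / 2, 0)), tolerance = 1e-12)

  # translation invariance of sd1, and the oracle on random records
  for (seed in 1:10) {
    withr::with_seed(seed, rrr <- runif(50, 0.7, 1.1))
    p1 <- poincare(ibi_series(cumsum(c(0, rrr))))
    p2 <- poincare(ibi_series(cumsum(c(0, rrr + 0.3))))
    expect_equal(p1$sd1, p2$sd1, tolerance = 1e-9)
    expect_equal(p1$sd1^2, var(diff(rrr)) / 2, tolerance = 1e-9)
    expect_equal(p1$sd2^2, 2 * var(rrr) - var(diff(rrr)) / 2, tolerance = 1e-9)
  }
})

test_that("Lomb-Scargle band powers locate injected oscillations", {
  hf <- gen_ibi(duration = 300, seed = 2, a_lf = 0, a_hf = 0.05, fluct_scale = 0)
  sp_hf <- ibi_spectrum(hf)
  expect_gt(sp_hf$hf_power, 10 * sp_hf$lf_power)
  expect_lt(sp_hf$lf_hf_ratio, 0.1)

  lf <- gen_ibi(duration = 300, seed = 2, a_lf = 0.05, a_hf = 0, fluct_scale = 0)
  expect_gt(ibi_spectrum(lf)$lf_hf_ratio, 10)

  const <- ibi_series(cumsum(c(0, rep(0.9, 60))))
  spc <- ibi_spectrum(const)
  expect_equal(spc$lf_power + spc$hf_power, 0)

  # band powers are additive over the full 0.04-0.4 Hz range
  pg <- attr(sp_hf, "periodogram")
  total <- sum(diff(pg$frequency) *
    (pg$power[-1] + pg$power[-nrow(pg)]) / 2)
  expect_equal(sp_hf$lf_power + sp_hf$hf_power, total, tolerance = 1e-9)
})

test_that("Lomb-Scargle agrees with the classical periodogram when even", {
  withr::with_seed(7, x <- 0.9 + 0.05 * sin(2 * pi * 0.21 * (1:256)) + rnorm(256, 0, 0.01))
  t <- 1:256 # 1 Hz sampling
  freqs <- seq(0.05, 0.45, by = 1 / 256)
  pw <- spiba:::lomb_scargle(t, x, freqs)
  sp <- stats::spec.pgram(ts(x, frequency = 1), plot = FALSE, taper = 0, detrend = TRUE)
  f_ls <- freqs[which.max(pw)]
  f_cl <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(f_ls - f_cl), 1 / 256 + 1e-9)
})

test_that("the Morse scalogram rides the instantaneous HRV frequency", {
  hf <- gen_ibi(duration = 300, seed = 2, a_lf = 0, a_hf = 0.05, fluct_scale = 0)
  sc <- ibi_scalogram(hf)
  ridge <- sc |>
    dplyr::group_by(time) |>
    dplyr::slice_max(magnitude, n = 1) |>
    dplyr::ungroup()
  mid <- ridge$frequency[ridge$time > 60 & ridge$time < 240]
  expect_true(all(abs(mid - 0.25) <= 0.03))

  # two-regime record: the ridge must transition across the boundary
  rr1 <- 0.9 + 0.05 * sin(2 * pi * 0.1 * cumsum(rep(0.9, 200)))
  t1 <- cumsum(c(0, rr1))
  rr2 <- 0.9 + 0.05 * sin(2 * pi * 0.3 * (max(t1) + cumsum(rep(0.9, 200))))
  both <- ibi_series(c(t1, max(t1) + cumsum(rr2)))
  sc2 <- ibi_scalogram(both)
  r2 <- sc2 |>
    dplyr::group_by(time) |>
    dplyr::slice_max(magnitude, n = 1) |>
    dplyr::ungroup()
  t_half <- max(t1)
  first <- median(r2$frequency[r2$time > 30 & r2$time < t_half - 30])
  second <- median(r2$frequency[r2$time > t_half + 30 & r2$time < max(r2$time) - 30])
  expect_lt(abs(first - 0.1), 0.03)
  expect_lt(abs(second - 0.3), 0.06)

  short <- ibi_series(cumsum(c(0, rep(0.9, 30))))
  expect_error(ibi_scalogram(short), "60 s")
})

test_that("windowed RR statistics follow the 30 s / 10 s overlap scheme", {
  rr <- rep(1, 120)
  ibi <- ibi_series(cumsum(c(0, rr)))
  w <- windowed_rr(ibi)
  expect_equal(nrow(w), floor((120 - 30) / 20) + 1)
  expect_true(all(w$mean_rr == 1))
  expect_true(all(w$median_rr == 1))
  expect_true(all(w$mode_rr == 1))

  short <- ibi_series(cumsum(c(0, rep(1, 20))))
  expect_warning(w2 <- windowed_rr(short), "shorter than one window")
  expect_equal(nrow(w2), 0)
})

test_that("cardiac spike signatures recover injected fluctuation structure", {
  tr <- gen_ibi(duration = 2000, seed = 11, a_lf = 0, a_hf = 0)
  fit <- cardiac_gamma(tr)
  truth <- attr(tr, "truth")
  expect_true(in_ci(truth$mms_shape, fit$gamma$shape_ci))
  expect_true(in_ci(truth$mms_scale, fit$gamma$scale_ci))

  const <- ibi_series(cumsum(c(0, rep(0.9, 300))))
  expect_error(cardiac_gamma(const), "\\[")

  # larger injected dispersion -> larger estimated NSR, monotone
  nsrs <- vapply(c(0.001, 0.003, 0.006), function(b) {
    sh <- 0.7^2 / (0.7 * b) # hold the spike mean at 0.7
    tri <- gen_ibi(
      duration = 1200, seed = 21, a_lf = 0, a_hf = 0,
      mms_shape = sh, mms_scale = b
    )
    cardiac_gamma(tri)$gamma$nsr
  }, numeric(1))
  expect_true(all(diff(nsrs) > 0))
})
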