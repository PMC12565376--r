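test_that("generators are pure functions of the seed", {
  expect_identical(gen_ibi(duration = 90, seed = 3), gen_ibi(duration = 90, seed = 3))
  expect_identical(
    gen_imu(duration = 60, seed = 3, task = "pointing"),
    gen_imu(duration = 60, seed = 3, task = "pointing")
  )
  expect_identical(gen_face(seed = 3), gen_face(seed = 3))
  v1 <- gen_voice(n_bursts = 10, seed = 3)
  v2 <- gen_voice(n_bursts = 10, seed = 3)
  expect_identical(v1$envelope, v2$envelope)
  expect_identical(
    gen_ecg(c(1, 2, 3), noise_sd = 0.1, seed = 3),
    gen_ecg(c(1, 2, 3), noise_sd = 0.1, seed = 3)
  )
})

test_that("the bump solver hits its target amplitudes exactly when feasible", {
  withr::with_seed(1, st <- spike_train(200, mms_shape = 240, mms_scale = 0.7 / 240))
  hit <- abs(st$truth$m_realized - st$truth$m_target) < 1e-12
  expect_gt(mean(hit), 0.99) # only out-of-band draws are clamped
  expect_true(all(st$d >= 0))
  expect_equal(length(st$d), 200 * 16 + 1)
})

test_that("RR generator honours baseline, oscillations and positivity", {
  const <- gen_ibi(duration = 90, seed = 1, a_lf = 0, a_hf = 0, fluct_scale = 0)
  expect_equal(const$value, rep(0.9, nrow(const)), tolerance = 1e-12)
  expect_error(gen_ibi(duration = 90, rr0 = 0.2), "nonpositive RR")

  hf <- gen_ibi(duration = 300, seed = 2, a_lf = 0, a_hf = 0.05, fluct_scale = 0)
  expect_lt(ibi_spectrum(hf)$lf_hf_ratio, 0.1)
})

test_that("ECG generator places recoverable beats", {
  beats <- seq(0.5, 119.5, by = 1)
  ecg <- gen_ecg(beats, fs = 250)
  ibi <- detect_rpeaks(preprocess_ecg(ecg))
  det <- attr(ibi, "beat_times")
  expect_equal(length(det), 120)
  expect_equal(nrow(ibi), 119)
  expect_lt(max(abs(det - attr(ecg, "truth")$beat_times)), 1 / 250 + 1e-9)

  expect_equal(max(abs(gen_ecg(numeric(0))$value)), 0)
  expect_error(gen_ecg(c(1, 1.01)), "separation")
})

test_that("noisy ECG still yields high R-peak recovery", {
  beats <- seq(0.5, 119.5, by = 1)
  ecg <- gen_ecg(beats, fs = 250, noise_sd = 0.13, seed = 5) # ~SNR 10 dB
  det <- attr(detect_rpeaks(preprocess_ecg(ecg)), "beat_times")
  tru <- attr(ecg, "truth")$beat_times
  tp <- sum(vapply(tru, function(b) any(abs(det - b) < 0.05), logical(1)))
  f1 <- 2 * tp / (length(det) + length(tru))
  expect_gte(f1, 0.95)
})

test_that("IMU task profiles order amplitude and fluctuation dispersion", {
  rest <- gen_imu(duration = 120, seed = 4, task = "resting", osc_amp = 0)
  walk <- gen_imu(duration = 120, seed = 4, task = "walking", osc_amp = 0)
  expect_lt(sd(accel_norm(rest)$value), sd(accel_norm(walk)$value))

  quiet <- gen_imu(duration = 60, seed = 1, fluct_scale = 0, osc_amp = 0)
  expect_equal(accel_norm(quiet)$value, rep(1, nrow(quiet)), tolerance = 1e-12)
})

test_that("face generator emits 150-frame clips with static fallback", {
  g <- gen_face(seed = 6)
  expect_equal(max(g$frame), 150)
  expect_equal(nrow(g), 150 * 68)

  frozen <- gen_face(seed = 6, movers_per_region = 0)
  sp <- landmark_speeds(frozen)
  expect_equal(max(sp$speed), 0)
})

test_that("voice generator produces exactly recoverable bursts", {
  v <- gen_voice(n_bursts = 60, seed = 5)
  segs <- segment_attack_decay(v$envelope)
  expect_equal(length(segs$maxima), v$truth$n_bursts)

  sl <- phase_slopes(v$envelope, segs)
  est <- sort(sl$slopes$slope[sl$slopes$phase == "attack"])
  expect_equal(est, sort(v$truth$attack_slopes), tolerance = 1e-9)
  expect_true(in_ci(2, sl$gamma_attack$scale_ci))

  silence <- gen_voice(n_bursts = 0, seed = 1)
  expect_equal(nrow(segment_attack_decay(silence$envelope)$segments), 0)
})
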