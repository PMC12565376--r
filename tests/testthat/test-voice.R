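test_that("gammatone filterbank layout matches the ERB design", {
  centers <- gammatone_centers()
  expect_length(centers, 10)
  expect_equal(centers[1], 100, tolerance = 1e-6)
  expect_equal(centers[10], 8000, tolerance = 1e-6)
  expect_true(all(diff(centers) > 0))
  # equal spacing on the ERB-number scale
  erb_num <- 21.4 * log10(4.37 * centers / 1000 + 1)
  expect_equal(diff(erb_num), rep(diff(erb_num)[1], 9), tolerance = 1e-6)
  # the default analysis band is the 4-7 kHz channel nearest 5600 Hz
  default_band <- which.min(abs(centers - 5600))
  expect_gt(centers[default_band], 4000)
  expect_lt(centers[default_band], 7000)
})

test_that("a tone at a band center concentrates envelope energy there", {
  fs <- 16000
  tt <- (0:(fs / 2 - 1)) / fs
  centers <- gammatone_centers()
  bd <- which.min(abs(centers - 5600))
  tone <- uniform_series(tt, sin(2 * pi * centers[bd] * tt), sampling_rate = fs)
  energies <- vapply(1:10, function(b) {
    mean(gammatone_envelope(tone, band = b, normalize = FALSE)$value^2)
  }, numeric(1))
  expect_equal(which.max(energies), bd)

  silence <- uniform_series(tt, rep(0, length(tt)), sampling_rate = fs)
  expect_equal(max(gammatone_envelope(silence, band = 8)$value), 0)
  expect_error(gammatone_envelope(tone, band = 11), "band")
})

test_that("median-threshold segmentation handles triangle waves exactly", {
  # 5 periods of a 0..1 triangle at 100 Hz sampling, 0.5 s period
  half <- 25
  one <- c(seq(0, 1, length.out = half + 1)[-(half + 1)], seq(1, 0, length.out = half + 1)[-(half + 1)])
  v <- c(rep(one, 5), 0)
  env <- uniform_series((seq_along(v) - 1) / 100, v, sampling_rate = 100)
  segs <- segment_attack_decay(env)
  expect_length(segs$maxima, 5)
  expect_length(segs$minima, 6)
  sl <- phase_slopes(env, segs, min_fit = 5)
  att <- sl$slopes$slope[sl$slopes$phase == "attack"]
  expect_equal(att, rep(1 / 0.25, 5), tolerance = 1e-9)
  dec <- sl$slopes$slope[sl$slopes$phase == "decay"]
  expect_equal(dec, rep(-1 / 0.25, 5), tolerance = 1e-9)
})

test_that("only the highest of competing maxima between minima is retained", {
  v <- c(0, 0.9, 0.3, 0.6, 0, 0.8, 0)
  env <- uniform_series((seq_along(v) - 1) / 10, v, sampling_rate = 10)
  segs <- segment_attack_decay(env)
  expect_equal(segs$maxima, c(2L, 6L))
  expect_equal(env$value[segs$maxima], c(0.9, 0.8))

  ramp <- uniform_series((0:9) / 10, (0:9) / 10, sampling_rate = 10)
  expect_equal(nrow(segment_attack_decay(ramp)$segments), 0)
})

test_that("time reversal swaps attack and decay statistics exactly", {
  v <- gen_voice(n_bursts = 30, seed = 9)
  env <- v$envelope
  rev_env <- uniform_series(env$time, rev(env$value),
    sampling_rate = sampling_rate(env)
  )
  f <- phase_slopes(env, segment_attack_decay(env), min_fit = 5)
  r <- phase_slopes(rev_env, segment_attack_decay(rev_env), min_fit = 5)
  expect_equal(
    sort(abs(f$slopes$slope[f$slopes$phase == "attack"])),
    sort(abs(r$slopes$slope[r$slopes$phase == "decay"])),
    tolerance = 1e-9
  )
})

test_that("phase areas are left-Riemann sums and add over a cycle", {
  fs <- 1000
  v <- rep(1, 1001)
  env <- uniform_series((0:1000) / fs, v, sampling_rate = fs)
  segs <- list(segments = tibble::tibble(
    phase = "attack", start = 1L, end = 1001L,
    start_time = 0, end_time = 1
  ))
  auc <- phase_auc(env, segs)
  expect_equal(auc$aucs$auc, 1.0, tolerance = 1e-12)

  ramp <- uniform_series((0:1000) / fs, (0:1000) / fs, sampling_rate = fs)
  auc2 <- phase_auc(ramp, segs)
  expect_lt(abs(auc2$aucs$auc - 0.5) / 0.5, 0.0011)

  # additivity over a full min-max-min cycle of a generated session
  vv <- gen_voice(n_bursts = 10, seed = 4)
  sg <- segment_attack_decay(vv$envelope)
  aa <- phase_auc(vv$envelope, sg)
  cyc <- sg$segments[1:2, ] # first attack + first decay share the maximum
  whole <- sum(vv$envelope$value[cyc$start[1]:(cyc$end[2] - 1)]) /
    sampling_rate(vv$envelope)
  expect_equal(sum(aa$aucs$auc[1:2]), whole, tolerance = 1e-12)

  # zero-length span
  segs0 <- list(segments = tibble::tibble(
    phase = "attack", start = 5L, end = 5L, start_time = 0.004, end_time = 0.004
  ))
  expect_equal(phase_auc(env, segs0)$aucs$auc, 0)
})

test_that("memory score averages the two digit spans", {
  expect_equal(memory_score(6, 4), 5)
  expect_equal(memory_score(0, 0), 0)
  expect_equal(memory_score(7, 5), 6)
  expect_error(memory_score(-1, 3), "nonnegative")
})

test_that("the full voice signature flags low-confidence fits", {
  v <- gen_voice(n_bursts = 60, seed = 5)
  vs <- voice_signature(v$envelope, longest_forward = 6, longest_backward = 4)
  expect_equal(vs$memory_score, 5)
  expect_equal(vs$n_attacks, 60)
  expect_true(in_ci(2, phase_slopes(
    v$envelope, segment_attack_decay(v$envelope)
  )$gamma_attack$scale_ci))

  few <- gen_voice(n_bursts = 8, seed = 2)
  sl <- phase_slopes(few$envelope, segment_attack_decay(few$envelope))
  expect_true(sl$low_confidence[["attack"]])
  expect_null(sl$gamma_attack)
})
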