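test_that("spike normalization follows Peak / (Peak + window average)", {
  # fabricated windows give exact control of the average
  d1 <- tibble::tibble(time = 1:3, value = c(3, 2, 1)) # mean 2
  pk1 <- tibble::tibble(
    peak = 2L, time = 2, value = 2, left_min = 1L, right_min = 3L
  )
  expect_equal(mms_normalize(d1, pk1)$amplitude, 0.5)

  d2 <- tibble::tibble(time = 1:5, value = c(4, 4, 1, 4, 2)) # mean 3
  pk2 <- tibble::tibble(
    peak = 3L, time = 3, value = 1, left_min = 1L, right_min = 5L
  )
  expect_equal(mms_normalize(d2, pk2)$amplitude, 0.25)

  expect_error(
    mms_normalize(d1, dplyr::mutate(pk1, value = -1)),
    "strictly positive"
  )
})

test_that("a sparse spike in a near-empty window drives the ratio towards 1", {
  v <- c(rep(0, 20), 5, rep(0, 20))
  s <- uniform_series(seq_along(v), v, sampling_rate = 1)
  out <- mms_normalize(s, detect_peaks(s))
  expect_gt(out$amplitude, 0.95)
  expect_lte(out$amplitude, 1)
})

test_that("spike amplitudes live in (0,1] and are invariant to rescaling", {
  for (seed in 1:5) {
    sim <- sim_spike_series(n_spikes = 60, seed = seed)
    fit <- mms(sim$data)
    expect_true(all(fit$spikes$amplitude > 0 & fit$spikes$amplitude <= 1))

    scaled <- dplyr::mutate(sim$data, value = value * 3.7)
    fit2 <- mms(scaled)
    expect_equal(fit2$spikes$amplitude, fit$spikes$amplitude, tolerance = 1e-9)
    expect_identical(fit2$spikes$time, fit$spikes$time)
  }
})

test_that("spike event times are a subset of source timestamps", {
  sim <- sim_spike_series(n_spikes = 50, seed = 9)
  fit <- mms(sim$data)
  expect_true(all(fit$spikes$time %in% sim$data$time))
})

test_that("the full pipeline recovers injected Gamma spike structure", {
  for (seed in c(11, 12)) {
    sim <- sim_spike_series(n_spikes = 250, seed = seed)
    fit <- mms(sim$data)
    expect_equal(fit$n_spikes, 250)
    expect_true(in_ci(240, fit$gamma$shape_ci))
    expect_true(in_ci(0.7 / 240, fit$gamma$scale_ci))
    # realized amplitudes match the generator's ground truth closely
    expect_lt(
      max(abs(sort(fit$spikes$amplitude) - sort(sim$truth$m_realized))), 1e-3
    )
  }
})

test_that("degenerate inputs fail with a labelled stage", {
  const <- tibble::tibble(time = 1:100, value = rep(2, 100))
  expect_error(mms(const), "peak detection \\(raw series\\)")
})
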