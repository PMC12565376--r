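# Shared fixtures built in code.

# A raw series whose deviation-stage spikes follow a known Gamma law:
# baseline minus an inverse-constructed bump train.
sim_spike_series <- function(n_spikes = 120, seed = 1, mms_shape = 240,
                             mms_scale = 0.7 / 240, baseline = 10, k = 8) {
  withr::with_seed(seed, {
    st <- spike_train(n_spikes, mms_shape = mms_shape, mms_scale = mms_scale, k = k)
    list(
      data = tibble::tibble(
        time = seq_along(st$d), value = baseline - st$d
      ),
      truth = st$truth
    )
  })
}

in_ci <- function(truth, ci) truth >= ci[1] && truth <= ci[2]

# random walk-ish positive envelope for property tests
random_envelope <- function(n = 400, seed = 1, fs = 100) {
  withr::with_seed(seed, {
    v <- abs(cumsum(rnorm(n))) + 0.1
    uniform_series((seq_len(n) - 1) / fs, v, sampling_rate = fs)
  })
}
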