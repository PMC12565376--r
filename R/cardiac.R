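#' Construct an inter-beat-interval series
#'
#' Non-uniform event series of R-peak times and the RR/IBI intervals between
#' consecutive beats. Intervals outside the physiologic band (default
#' 0.3-2.0 s) are flagged as artifacts and excluded from the Poincare,
#' spectral and Gamma computations downstream.
#'
#' @param beat_times R-peak times in seconds, strictly increasing.
#' @param physiologic_band Two-element numeric: valid RR range in seconds.
#' @return A tibble of class `ibi_series`: `time` (start beat of each
#'   interval), `value` (the interval in seconds), `valid` (inside the
#'   physiologic band). The full beat-time vector is kept as an attribute.
#' @export
ibi_series <- function(beat_times, physiologic_band = c(0.3, 2.0)) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    stop("need at least 2 beats to form an interval", call. = FALSE)
  }
  rr <- diff(beat_times)
  if (any(rr <= 0)) stop("beat times must be strictly increasing", call. = FALSE)
  out <- tibble::tibble(
    time = beat_times[-length(beat_times)],
    value = rr,
    valid = rr >= physiologic_band[1] & rr <= physiologic_band[2]
  )
  class(out) <- c("ibi_series", class(out))
  attr(out, "beat_times") <- beat_times
  attr(out, "physiologic_band") <- physiologic_band
  out
}

valid_rr <- function(ibi) ibi$value[ibi$valid]

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf(
    "<ibi_series> %d intervals (%d artifact-flagged), mean RR %.3f s\n",
    nrow(x), sum(!x$valid), mean(x$value)
  ))
  NextMethod()
}

#' Band-pass and band-stop filter a raw ECG trace
#'
#' Preprocessing for QRS detection: an 8th-order Butterworth band-pass over
#' 5-30 Hz (the QRS energy band) followed by a 2nd-order Butterworth
#' band-stop over 40-125 Hz, both applied forward-backward (zero phase) so
#' R-peak timing is preserved. At a 250 Hz sampling rate the stop band's
#' upper edge touches Nyquist and is clipped to 0.99 x Nyquist.
#'
#' @param data A [uniform_series()] of raw ECG in mV.
#' @param band_pass Pass band in Hz (default `c(5, 30)`).
#' @param band_stop Stop band in Hz (default `c(40, 125)`).
#' @return A [uniform_series()] of the filtered ECG, same timestamps.
#' @export
preprocess_ecg <- function(data, band_pass = c(5, 30), band_stop = c(40, 125)) {
  fs <- sampling_rate(data)
  nyq <- fs / 2
  if (band_pass[2] >= nyq) {
    stop("sampling rate too low for the 5-30 Hz pass band", call. = FALSE)
  }
  # forward-backward filtering squares the magnitude response; widen the
  # design edges so the cascade's -3 dB points sit at the stated band edges
  # (prototype scale (sqrt(2)-1)^(1/(2*order)))
  adj <- (sqrt(2) - 1)^(1 / 8)
  design_band <- c(band_pass[1] * adj, min(band_pass[2] / adj, 0.999 * nyq))
  bp <- signal::butter(4, design_band / nyq, type = "pass")
  x <- filtfilt_padded(bp, data$value - mean(data$value), fs)
  stop_hi <- min(band_stop[2], 0.99 * nyq)
  if (band_stop[1] < stop_hi) {
    # same cascade-edge convention for the stop band: pick the design lower
    # edge so the forward-backward response is -3 dB at the stated edge
    lo_design <- tryCatch(
      stats::uniroot(
        function(lo) {
          butter_gain2(signal::butter(1, c(lo, stop_hi) / nyq, type = "stop"),
            band_stop[1] / fs
          ) - 1 / sqrt(2)
        },
        c(band_stop[1], 0.98 * stop_hi)
      )$root,
      error = function(e) band_stop[1]
    )
    bs <- signal::butter(1, c(lo_design, stop_hi) / nyq, type = "stop")
    x <- filtfilt_padded(bs, x, fs)
  }
  reseries(data, x)
}

# squared magnitude response of a digital filter at cycles-per-sample f
butter_gain2 <- function(flt, f) {
  z <- exp(-2i * pi * f)
  Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
    sum(flt$a * z^(seq_along(flt$a) - 1)))^2
}

# Zero-phase filtering with reflective edge padding (one second or a third
# of the record, whichever is smaller) so startup transients decay inside
# the pad rather than in the data.
filtfilt_padded <- function(flt, x, fs) {
  n <- length(x)
  np <- min(ceiling(fs), floor((n - 1) / 3))
  if (np < 1) {
    return(as.numeric(signal::filtfilt(flt, x)))
  }
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  as.numeric(y[(np + 1):(np + n)])
}

#' Detect R peaks in a filtered ECG
#'
#' Simple two-stage adaptive peak detection. Candidate peaks must rise at
#' least `threshold_k * median(|x|)` above their flanking minima and be
#' separated by at least the refractory period; a second adaptive pass then
#' drops candidates below `beat_frac` of the upper-quartile candidate
#' height, which rejects filter-ringing sidelobes and noise excursions that
#' survive the first stage while true beats set the reference level.
#'
#' @param data A filtered ECG [uniform_series()] (see [preprocess_ecg()]).
#' @param refractory Minimum beat separation in seconds (default 0.25).
#' @param threshold_k Prominence multiplier on `median(|x|)` (default 4).
#' @param beat_frac Second-stage fraction of the 75th-percentile candidate
#'   height (default 0.4); 0 disables the second stage.
#' @param ... Passed to [ibi_series()].
#' @return An [ibi_series()].
#' @export
detect_rpeaks <- function(data, refractory = 0.25, threshold_k = 4,
                          beat_frac = 0.4, ...) {
  thr <- threshold_k * stats::median(abs(data$value))
  if (thr <= 0) stop("insufficient beats: flat signal", call. = FALSE)
  pk <- detect_peaks(data, min_separation = refractory, min_prominence = thr)
  if (beat_frac > 0 && nrow(pk) > 0) {
    level <- stats::quantile(pk$value, 0.75, names = FALSE)
    pk <- pk[pk$value >= beat_frac * level, ]
  }
  if (nrow(pk) < 2) {
    stop("insufficient beats: fewer than 2 R-peaks detected", call. = FALSE)
  }
  ibi_series(pk$time, ...)
}

#' Poincare descriptors of an IBI series
#'
#' Time-domain heart-rate-variability metrics from the lag-1 scatter of each
#' interval against its predecessor. SD1 (the width of the ellipse,
#' parasympathetic proxy) and SD2 (its length, sympathetic proxy) are
#' computed from the closed forms
#' `sd1^2 = Var(successive differences) / 2` and
#' `sd2^2 = 2 Var(RR) - Var(successive differences) / 2`.
#'
#' @param ibi An [ibi_series()]; artifact-flagged intervals are excluded.
#' @return A one-row tibble: `sd1`, `sd2`, `ratio_sd2_sd1`, `n`.
#' @export
poincare <- function(ibi) {
  rr <- valid_rr(ibi)
  if (length(rr) < 3) {
    stop("insufficient data: need at least 3 valid intervals", call. = FALSE)
  }
  vd <- stats::var(diff(rr))
  vr <- stats::var(rr)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(2 * vr - vd / 2, 0))
  tibble::tibble(
    sd1 = sd1, sd2 = sd2,
    ratio_sd2_sd1 = ifelse(sd1 > 0, sd2 / sd1, NA_real_),
    n = length(rr)
  )
}

# Classical normalized Lomb-Scargle periodogram for unevenly sampled data.
lomb_scargle <- function(t, y, freqs) {
  y <- y - mean(y)
  var_y <- stats::var(y)
  if (var_y == 0) {
    return(rep(0, length(freqs)))
  }
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * var_y)
  }, numeric(1))
}

#' Frequency-domain HRV metrics from the Lomb-Scargle periodogram
#'
#' Power spectral density of the (unevenly sampled) IBI series via the
#' classical normalized Lomb-Scargle periodogram, with band powers obtained
#' by trapezoidal integration over the low-frequency (0.04-0.15 Hz,
#' sympathetic/baroreflex) and high-frequency (0.15-0.4 Hz, parasympathetic/
#' respiratory) bands. The LF/HF ratio indexes sympatho-vagal balance.
#'
#' @param ibi An [ibi_series()] with at least 30 valid intervals.
#' @param lf_band,hf_band Band edges in Hz.
#' @param df Frequency grid step in Hz (default 0.005).
#' @return A one-row tibble: `lf_power`, `hf_power`, `lf_hf_ratio`,
#'   `lf_resolved` (FALSE when the record is too short to resolve 0.04 Hz),
#'   plus the periodogram as the `periodogram` attribute (tibble
#'   `frequency`, `power`).
#' @export
ibi_spectrum <- function(ibi, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                         df = 0.005) {
  keep <- ibi$valid
  t <- ibi$time[keep]
  y <- ibi$value[keep]
  if (length(y) < 30) {
    stop("need at least 30 valid intervals for spectral metrics", call. = FALSE)
  }
  span <- diff(range(t))
  lf_resolved <- span >= 2 / lf_band[1]
  freqs <- seq(lf_band[1], hf_band[2], by = df)
  pw <- if (stats::sd(y) <= 1e-9 * mean(y)) {
    # constant record up to floating-point wiggle: no oscillatory power
    rep(0, length(freqs))
  } else {
    lomb_scargle(t, y, freqs)
  }
  band_power <- function(band) {
    sel <- freqs >= band[1] & freqs <= band[2]
    f <- freqs[sel]
    p <- pw[sel]
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  out <- tibble::tibble(
    lf_power = lf, hf_power = hf,
    lf_hf_ratio = ifelse(hf > 0, lf / hf, NA_real_),
    lf_resolved = lf_resolved
  )
  attr(out, "periodogram") <- tibble::tibble(frequency = freqs, power = pw)
  out
}

# Generalized Morse wavelet (gamma = 3, beta = 20; the common default
# time-bandwidth P^2 = 60) evaluated in the frequency domain.
morse_filter <- function(omega, gamma = 3, beta = 20) {
  h <- numeric(length(omega))
  pos <- omega > 0
  lg <- beta * log(omega[pos]) - omega[pos]^gamma
  peak <- (beta / gamma)^(1 / gamma)
  lg0 <- beta * log(peak) - peak^gamma
  h[pos] <- 2 * exp(lg - lg0)
  h
}

#' Morse-wavelet magnitude scalogram of an IBI series
#'
#' Continuous wavelet transform with the generalized Morse wavelet, for
#' visualizing which HRV frequencies dominate over time. The uneven IBI
#' sequence is first linearly interpolated onto a uniform grid (default
#' 4 Hz); scales are expressed as equivalent Fourier frequencies and the
#' output restricted to the 0.04-0.4 Hz HRV band.
#'
#' @param ibi An [ibi_series()] spanning at least 60 s.
#' @param resample_rate Uniform resampling rate in Hz (default 4).
#' @param freqs Frequency axis in Hz (default 48 log-spaced points in
#'   0.04-0.4 Hz).
#' @param gamma,beta Morse wavelet parameters (defaults 3 and 20).
#' @return A tibble of class `ibi_scalogram` in long format: `time`,
#'   `frequency`, `magnitude`.
#' @export
ibi_scalogram <- function(ibi, resample_rate = 4,
                          freqs = exp(seq(log(0.04), log(0.4), length.out = 48)),
                          gamma = 3, beta = 20) {
  keep <- ibi$valid
  t <- ibi$time[keep]
  y <- ibi$value[keep]
  if (diff(range(t)) < 60) {
    stop("insufficient data: record shorter than 60 s", call. = FALSE)
  }
  tg <- seq(min(t), max(t), by = 1 / resample_rate)
  yg <- stats::approx(t, y, xout = tg)$y
  yg <- yg - mean(yg)
  n <- length(yg)
  omega <- 2 * pi * (seq_len(n) - 1) / n # radians per sample
  xf <- stats::fft(yg)
  peak <- (beta / gamma)^(1 / gamma)
  rows <- purrr::map_dfr(freqs, function(f) {
    s <- peak / (2 * pi * f / resample_rate) # scale in samples
    h <- morse_filter(omega * s, gamma, beta)
    w <- stats::fft(xf * h, inverse = TRUE) / n
    tibble::tibble(time = tg, frequency = f, magnitude = Mod(w))
  })
  class(rows) <- c("ibi_scalogram", class(rows))
  rows
}

#' Windowed RR statistics
#'
#' Gaussian moments of the RR distribution over sliding windows: mean,
#' median, and mode (mode from a histogram with 10 ms bins, ties resolved to
#' the earliest bin). Default 30 s windows with 10 s overlap, i.e. a 20 s
#' step; the last partial window is dropped. Intervals are assigned to a
#' window by the time of their starting beat.
#'
#' @param ibi An [ibi_series()].
#' @param window Window length in seconds (default 30).
#' @param overlap Window overlap in seconds (default 10).
#' @param mode_bin Histogram bin width for the mode, in seconds (default 0.01).
#' @return A tibble with one row per window: `start`, `end`, `mean_rr`,
#'   `median_rr`, `mode_rr`, `n`, `sufficient` (at least 3 intervals).
#' @export
windowed_rr <- function(ibi, window = 30, overlap = 10, mode_bin = 0.01) {
  step <- window - overlap
  if (step <= 0) stop("`overlap` must be smaller than `window`", call. = FALSE)
  t0 <- min(ibi$time)
  span <- max(attr(ibi, "beat_times")) - t0
  if (span < window) {
    warning("record shorter than one window; returning zero windows")
    return(tibble::tibble(
      start = numeric(), end = numeric(), mean_rr = numeric(),
      median_rr = numeric(), mode_rr = numeric(), n = integer(),
      sufficient = logical()
    ))
  }
  starts <- seq(t0, t0 + span - window, by = step)
  purrr::map_dfr(starts, function(s) {
    rr <- ibi$value[ibi$valid & ibi$time >= s & ibi$time < s + window]
    n <- length(rr)
    if (n >= 3) {
      bins <- floor(rr / mode_bin)
      tab <- table(bins)
      # mode = median of the intervals in the most populated 10 ms bin
      # (ties to the earliest bin); exact for repeated values
      win <- as.numeric(names(tab)[which.max(tab)])
      mode_rr <- stats::median(rr[bins == win])
      tibble::tibble(
        start = s, end = s + window, mean_rr = mean(rr),
        median_rr = stats::median(rr), mode_rr = mode_rr, n = n,
        sufficient = TRUE
      )
    } else {
      tibble::tibble(
        start = s, end = s + window, mean_rr = NA_real_,
        median_rr = NA_real_, mode_rr = NA_real_, n = n, sufficient = FALSE
      )
    }
  })
}

#' Spike standardization and Gamma signature of an IBI series
#'
#' Applies the micro-movement spike pipeline ([mms()]) to the RR intervals
#' treated as an amplitude sequence over beat times, yielding the cardiac
#' Gamma shape/scale signature (scale = noise-to-signal ratio of the IBI
#' fluctuations).
#'
#' @param ibi An [ibi_series()]; artifact-flagged intervals are excluded.
#' @param ... Passed to [mms()] (peak constraints, `min_spikes`).
#' @return An `mms_result` (see [mms()]).
#' @export
cardiac_gamma <- function(ibi, ...) {
  keep <- ibi$valid
  mms(tibble::tibble(time = ibi$time[keep], value = ibi$value[keep]), ...)
}
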