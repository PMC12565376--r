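#' Normalize deviation peaks into micro-movement spikes
#'
#' Applies the allometric spike normalization to a set of peaks of a
#' (deviation) series: each spike amplitude is
#' \deqn{MMS = \frac{Peak}{Peak + Avrg_{min\,to\,min}}}
#' where `Avrg` is the arithmetic mean of all samples between (and including)
#' the two local minima flanking the peak. The ratio is unitless, bounded in
#' (0,1], and invariant to uniform rescaling of the signal, which removes
#' anatomical (allometric) amplitude differences across people and body
#' parts. Event timestamps are inherited from the source series, so spikes
#' remain aligned with the original recording.
#'
#' @param data The series the peaks were detected on (`time`, `value`).
#' @param peaks A `peak_set` from [detect_peaks()] on `data`; every peak value
#'   must be strictly positive.
#' @return A tibble of class `mms_series`: `time`, `amplitude` in (0,1],
#'   `peak` (sample index), `peak_value`, `window_mean`.
#' @examples
#' s <- uniform_series(0:4, c(0, 2, 0, 1, 0), sampling_rate = 1)
#' mms_normalize(s, detect_peaks(s))
#' @export
mms_normalize <- function(data, peaks) {
  if (nrow(peaks) > 0 && any(peaks$value <= 0)) {
    stop("every peak amplitude must be strictly positive for spike normalization",
      call. = FALSE
    )
  }
  x <- data$value
  avrg <- purrr::map2_dbl(peaks$left_min, peaks$right_min, function(l, r) {
    mean(x[l:r])
  })
  denom <- peaks$value + avrg
  if (any(denom == 0)) {
    stop("degenerate window: Peak + Avrg equals zero", call. = FALSE)
  }
  out <- tibble::tibble(
    time = peaks$time,
    amplitude = peaks$value / denom,
    peak = peaks$peak,
    peak_value = peaks$value,
    window_mean = avrg
  )
  class(out) <- c("mms_series", class(out))
  out
}

# Stage 1-5 of the spike pipeline without the final Gamma fit; used by
# modality code that pools spikes across channels before fitting.
mms_spikes <- function(data, min_separation = 0, min_prominence = 0,
                       stage1_min_separation = 0, stage1_min_prominence = 0,
                       value_col = "value") {
  p1 <- with_stage(
    "peak detection (raw series)",
    detect_peaks(data, stage1_min_separation, stage1_min_prominence,
      value_col = value_col
    )
  )
  if (nrow(p1) == 0) {
    stop("[peak detection (raw series)] no peaks found", call. = FALSE)
  }
  amp1 <- p1$value[p1$value > 0]
  g1 <- with_stage(
    "empirical Gamma mean of raw peaks",
    gamma_fit(amp1)
  )
  dev <- data
  dev$value <- abs(data[[value_col]] - g1$mean)
  p2 <- with_stage(
    "peak detection (deviation series)",
    detect_peaks(dev, min_separation, min_prominence)
  )
  p2 <- p2[p2$value > 0, ]
  spikes <- with_stage(
    "spike normalization",
    mms_normalize(dev, p2)
  )
  list(spikes = spikes, stage1_gamma = g1, deviations = dev)
}

with_stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Micro-movement spike pipeline
#'
#' The full spike standardization of a biorhythmic series:
#' 1. detect peaks of the raw series;
#' 2. fit a Gamma distribution to the (positive) peak amplitudes by MLE and
#'    take its mean as the empirical reference amplitude;
#' 3. form the absolute deviations of the series from that mean;
#' 4. detect peaks of the deviation series;
#' 5. normalize each deviation peak by its min-to-min window average
#'    ([mms_normalize()]);
#' 6. fit the Gamma signature of the resulting spike amplitudes.
#'
#' The result carries both the unitless spike train (timestamps preserved
#' from the input) and the final Gamma signature whose scale is the
#' noise-to-signal ratio of the signal.
#'
#' @inheritParams detect_peaks
#' @param min_separation,min_prominence Peak constraints for the deviation
#'   (spike) stage; defaults 0 (pure local extrema).
#' @param stage1_min_separation,stage1_min_prominence Peak constraints for the
#'   raw-series stage; defaults 0.
#' @param min_spikes Minimum number of spikes required for the final Gamma
#'   fit (default 20).
#' @return An object of class `mms_result`: list with `spikes` (an
#'   `mms_series` tibble), `gamma` (the spike `gamma_signature`),
#'   `stage1_gamma`, and `n_spikes`.
#' @examples
#' tr <- gen_ibi(duration = 240, seed = 7, a_lf = 0, a_hf = 0)
#' fit <- mms(tibble::tibble(time = tr$time, value = tr$value))
#' glance(fit)
#' @export
mms <- function(data, min_separation = 0, min_prominence = 0,
                stage1_min_separation = 0, stage1_min_prominence = 0,
                min_spikes = 20, value_col = "value") {
  st <- mms_spikes(data,
    min_separation = min_separation, min_prominence = min_prominence,
    stage1_min_separation = stage1_min_separation,
    stage1_min_prominence = stage1_min_prominence, value_col = value_col
  )
  g2 <- with_stage(
    "Gamma fit of spike amplitudes",
    gamma_fit(st$spikes$amplitude, min_n = min_spikes)
  )
  out <- list(
    spikes = st$spikes, gamma = g2, stage1_gamma = st$stage1_gamma,
    n_spikes = nrow(st$spikes)
  )
  class(out) <- "mms_result"
  out
}

#' @export
print.mms_result <- function(x, ...) {
  cat(sprintf("<mms_result> %d spikes\n", x$n_spikes))
  print(x$gamma)
  invisible(x)
}

#' @export
tidy.mms_result <- function(x, ...) {
  tibble::as_tibble(x$spikes)
}

#' @export
glance.mms_result <- function(x, ...) {
  dplyr::mutate(glance(x$gamma), n_spikes = x$n_spikes)
}
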