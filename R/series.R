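#' Construct a uniformly sampled signal
#'
#' The basic container for raw biorhythmic recordings: a tibble with a `time`
#' column in seconds and a `value` column in the units of the modality (mV for
#' ECG, g for acceleration, normalized units/s for facial speeds, unitless for
#' audio envelopes). Sampling rate and units travel as attributes so that
#' downstream filters and spectral estimators know the grid without
#' re-deriving it.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing
#'   and uniformly spaced.
#' @param value Numeric vector of signal amplitudes, same length as `time`.
#' @param sampling_rate Sampling rate in Hz. If `NULL`, inferred from the
#'   median spacing of `time`.
#' @param units Character scalar naming the amplitude units (metadata only).
#'
#' @return A tibble of class `uniform_series` with columns `time` and `value`
#'   and attributes `sampling_rate` and `units`.
#' @examples
#' s <- uniform_series(seq(0, 1, by = 0.01), sin(2 * pi * seq(0, 1, by = 0.01)))
#' sampling_rate(s)
#' @export
uniform_series <- function(time, value, sampling_rate = NULL, units = "") {
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("`time` must be strictly increasing", call. = FALSE)
    step <- stats::median(dt)
    if (any(abs(dt - step) > 1e-6 * step)) {
      stop("`time` must be uniformly spaced (tolerance 1e-6 relative)", call. = FALSE)
    }
    fs <- 1 / step
    if (is.null(sampling_rate)) {
      sampling_rate <- fs
    } else if (abs(fs - sampling_rate) > 1e-6 * sampling_rate) {
      stop("`sampling_rate` disagrees with the spacing of `time`", call. = FALSE)
    }
  }
  if (is.null(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  class(out) <- c("uniform_series", class(out))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "units") <- units
  out
}

#' @rdname uniform_series
#' @param x A `uniform_series`.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "sampling_rate")
  if (is.null(fs)) {
    dt <- diff(x$time)
    fs <- 1 / stats::median(dt)
  }
  fs
}

#' @rdname uniform_series
#' @export
series_units <- function(x) attr(x, "units") %||% ""

# Rebuild a uniform_series with new values on the same grid.
reseries <- function(template, value, units = series_units(template)) {
  uniform_series(template$time, value,
    sampling_rate = sampling_rate(template), units = units
  )
}

#' Construct a triaxial acceleration series
#'
#' Container for IMU output: three acceleration axes in g at a common sampling
#' rate (31.25 Hz for the chest/arm/leg wearables this package targets), with
#' body location and task labels from closed vocabularies.
#'
#' @param time,x,y,z Numeric vectors of equal length; time in seconds,
#'   axes in g.
#' @param location One of `"pectoralis"`, `"arm"`, `"leg"`.
#' @param task One of `"resting"`, `"pointing"`, `"walking"`, `"daily"`,
#'   `"sleep"`.
#' @param sampling_rate Sampling rate in Hz (default 31.25).
#' @param participant Optional participant identifier.
#' @return A tibble of class `triaxial_series` with columns `time`, `x`, `y`,
#'   `z` and metadata attributes.
#' @export
triaxial_series <- function(time, x, y, z, location = "pectoralis",
                            task = "resting", sampling_rate = NULL,
                            participant = NA_character_) {
  location <- match.arg(location, c("pectoralis", "arm", "leg"))
  task <- match.arg(task, c("resting", "pointing", "walking", "daily", "sleep"))
  n <- length(time)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("time, x, y, z must have equal lengths", call. = FALSE)
  }
  base <- uniform_series(time, x, sampling_rate = sampling_rate, units = "g")
  out <- tibble::tibble(
    time = as.numeric(time), x = as.numeric(x),
    y = as.numeric(y), z = as.numeric(z)
  )
  class(out) <- c("triaxial_series", class(out))
  attr(out, "sampling_rate") <- sampling_rate(base)
  attr(out, "units") <- "g"
  attr(out, "location") <- location
  attr(out, "task") <- task
  attr(out, "participant") <- participant
  out
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf(
    "<uniform_series> %d samples at %.6g Hz%s\n", nrow(x), sampling_rate(x),
    if (nzchar(series_units(x))) paste0(" [", series_units(x), "]") else ""
  ))
  NextMethod()
}

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf(
    "<triaxial_series> %d samples at %.6g Hz, location=%s task=%s\n",
    nrow(x), sampling_rate(x), attr(x, "location"), attr(x, "task")
  ))
  NextMethod()
}
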