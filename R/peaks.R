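#' Detect local peaks and their flanking minima
#'
#' Finds strict local maxima of a sampled signal together with the local
#' minima immediately flanking each peak. These min-to-min windows are the
#' unit of the micro-movement spike normalization: the spike amplitude is
#' `Peak / (Peak + Avrg)` where `Avrg` averages the signal between the two
#' flanking minima (see [mms_normalize()]).
#'
#' Conventions (the signal-level rules this package fixes):
#' * a peak is a strict local maximum; plateaus are collapsed and represented
#'   by their first sample; boundary samples are never peaks;
#' * `min_prominence` filters on topographic prominence: the peak height
#'   above the higher of the two saddle minima reached before the signal
#'   next exceeds the peak (or the record ends). Micro-ripple near a summit
#'   therefore never masks the summit's true prominence;
#' * peaks closer than `min_separation` are resolved keeping the larger;
#' * the flanking minima of each retained peak are the deepest troughs
#'   (earliest sample on ties) between it and the neighbouring retained
#'   peaks, or between it and the record boundary for the outermost peaks —
#'   so each min-to-min window spans trough to trough.
#'
#' @param data A data frame with `time` and `value` columns ([uniform_series()]
#'   or any strictly time-ordered series, e.g. an inter-beat-interval
#'   sequence indexed by beat time).
#' @param min_separation Minimum time separation between retained peaks, in
#'   seconds. Default 0 (pure local-extremum detection).
#' @param min_prominence Minimum prominence above the higher flanking minimum,
#'   in signal units. Default 0.
#' @param value_col Name of the value column (default `"value"`).
#'
#' @return A tibble of class `peak_set`, one row per retained peak:
#'   `peak` (sample index), `time`, `value`, `left_min`, `right_min`
#'   (flanking minimum sample indices) plus their times and values.
#' @examples
#' s <- uniform_series(0:4, c(0, 1, 0, 2, 0), sampling_rate = 1)
#' detect_peaks(s)
#' @export
detect_peaks <- function(data, min_separation = 0, min_prominence = 0,
                         value_col = "value") {
  if (nrow(data) < 3) {
    stop("series must have at least 3 samples for peak detection", call. = FALSE)
  }
  if (min_separation < 0) stop("`min_separation` must be >= 0", call. = FALSE)
  x <- data[[value_col]]
  tm <- data$time
  ext <- local_extrema(x)
  max_idx <- ext$maxima
  if (length(max_idx) == 0) {
    return(empty_peak_set())
  }

  if (min_prominence > 0) {
    prom <- vapply(max_idx, function(i) peak_prominence(x, i), numeric(1))
    max_idx <- max_idx[prom >= min_prominence]
  }
  if (length(max_idx) == 0) {
    return(empty_peak_set())
  }

  if (min_separation > 0 && length(max_idx) > 1) {
    ord <- order(x[max_idx], decreasing = TRUE)
    kept <- logical(length(max_idx))
    kept_times <- numeric(0)
    for (i in ord) {
      ti <- tm[max_idx[i]]
      if (all(abs(kept_times - ti) >= min_separation)) {
        kept[i] <- TRUE
        kept_times <- c(kept_times, ti)
      }
    }
    max_idx <- sort(max_idx[kept])
  }

  # deepest trough (earliest on ties) between consecutive retained peaks
  # and between the outermost peaks and the record ends
  bounds <- c(1L, max_idx, length(x))
  np <- length(max_idx)
  left <- right <- integer(np)
  for (i in seq_len(np)) {
    lo <- bounds[i]
    hi <- max_idx[i]
    seg <- if (lo == 1L) lo:(hi - 1L) else (lo + 1L):(hi - 1L)
    left[i] <- seg[which.min(x[seg])]
    lo <- max_idx[i]
    hi <- bounds[i + 2L]
    seg <- if (hi == length(x) && !(hi %in% max_idx)) (lo + 1L):hi else (lo + 1L):(hi - 1L)
    right[i] <- seg[which.min(x[seg])]
  }

  out <- tibble::tibble(
    peak = max_idx, time = tm[max_idx], value = x[max_idx],
    left_min = left, left_min_time = tm[left], left_min_value = x[left],
    right_min = right, right_min_time = tm[right], right_min_value = x[right]
  )
  class(out) <- c("peak_set", class(out))
  out
}

empty_peak_set <- function() {
  out <- tibble::tibble(
    peak = integer(), time = numeric(), value = numeric(),
    left_min = integer(), left_min_time = numeric(), left_min_value = numeric(),
    right_min = integer(), right_min_time = numeric(), right_min_value = numeric()
  )
  class(out) <- c("peak_set", class(out))
  out
}

# Topographic prominence of the peak at index i: height above the higher of
# the two saddle minima found before the signal next exceeds x[i] (or the
# record ends) on each side.
peak_prominence <- function(x, i) {
  v <- x[i]
  lmin <- v
  j <- i - 1L
  while (j >= 1L && x[j] <= v) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  rmin <- v
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= v) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  v - max(lmin, rmin)
}

# Strict local extrema with plateau collapsing. A plateau is represented by
# its first sample. Boundary runs are eligible minima (below their single
# neighbour) but never maxima.
local_extrema <- function(x) {
  r <- rle(x)
  m <- length(r$values)
  if (m < 2) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  starts <- cumsum(c(1L, r$lengths[-m]))
  v <- r$values
  is_max <- is_min <- logical(m)
  if (m >= 3) {
    mid <- 2:(m - 1)
    is_max[mid] <- v[mid] > v[mid - 1] & v[mid] > v[mid + 1]
    is_min[mid] <- v[mid] < v[mid - 1] & v[mid] < v[mid + 1]
  }
  is_min[1] <- v[1] < v[2]
  is_min[m] <- v[m] < v[m - 1]
  list(maxima = starts[is_max], minima = starts[is_min])
}

#' Absolute deviations from an empirical Gamma mean
#'
#' Subtracts the empirically estimated Gamma mean from every sample and takes
#' absolute values, producing the nonnegative fluctuation field whose peaks
#' become micro-movement spikes. Timestamps are preserved exactly.
#'
#' @param data A series with `time` and `value` columns.
#' @param gamma_mean The empirical Gamma mean amplitude (positive scalar),
#'   typically `glance(gamma_fit(peaks$value))$mean`.
#' @return A series of the same class and timestamps with
#'   `value = |value - gamma_mean|`.
#' @export
deviation_series <- function(data, gamma_mean) {
  if (!is.numeric(gamma_mean) || length(gamma_mean) != 1 || gamma_mean <= 0) {
    stop("`gamma_mean` must be a positive scalar", call. = FALSE)
  }
  out <- data
  out$value <- abs(data$value - gamma_mean)
  out
}
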