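erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' ERB-spaced gammatone center frequencies
#'
#' Ten channel centers equally spaced on the Glasberg-Moore ERB-rate scale
#' between 100 and 8000 Hz. Band 8 lands in the 4-7 kHz range that has
#' proven informative for speech-envelope stochastics.
#'
#' @param n_bands Number of channels (default 10).
#' @param f_lo,f_hi Frequency range in Hz (defaults 100, 8000).
#' @return Numeric vector of center frequencies in Hz.
#' @export
gammatone_centers <- function(n_bands = 10, f_lo = 100, f_hi = 8000) {
  erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
  erb_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
  erb_inv(seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n_bands))
}

#' Gammatone band envelope of an audio signal
#'
#' Filters the audio with a 4th-order gammatone filter at the requested
#' band's ERB-spaced center (applied zero-phase in the frequency domain with
#' the gammatone magnitude response), then extracts the amplitude envelope
#' by half-wave rectification and a 4th-order Butterworth low-pass at
#' `env_cutoff` Hz. The envelope is the smoothed curve outlining the
#' waveform's amplitude variations over time.
#'
#' @param audio A [uniform_series()] of mono audio in [-1, 1].
#' @param band Band index 1-10, or `NULL` (default) for the band whose
#'   center is closest to 5600 Hz — the 4-7 kHz channel that has proven
#'   informative for speech stochastics. (Under the equal-ERB layout used
#'   here that is band 9; filterbank numbering conventions differ across
#'   toolboxes, so the band is selected by its center frequency.)
#' @param n_bands,f_lo,f_hi Filterbank layout (see [gammatone_centers()]).
#' @param env_cutoff Envelope low-pass cutoff in Hz (default 20).
#' @param normalize If `TRUE` (default) rescale the session so its envelope
#'   maximum is 1 (unitless amplitudes).
#' @return A [uniform_series()] of nonnegative envelope amplitudes with
#'   attributes `band_index` and `band_center`.
#' @export
gammatone_envelope <- function(audio, band = NULL, n_bands = 10, f_lo = 100,
                               f_hi = 8000, env_cutoff = 20, normalize = TRUE) {
  fs <- sampling_rate(audio)
  centers <- gammatone_centers(n_bands, f_lo, f_hi)
  if (is.null(band)) band <- which.min(abs(centers - 5600))
  if (band < 1 || band > n_bands) {
    stop(sprintf("`band` must be in 1-%d", n_bands), call. = FALSE)
  }
  fc <- centers[band]
  x <- audio$value
  n <- length(x)
  # 4th-order gammatone magnitude response, zero phase
  f <- (seq_len(n) - 1) / n * fs
  f <- ifelse(f > fs / 2, f - fs, f)
  b <- 1.019 * erb_bandwidth(fc)
  h <- (1 + ((abs(f) - fc) / b)^2)^(-2)
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
  env <- pmax(y, 0)
  lp <- signal::butter(4, min(env_cutoff / (fs / 2), 0.99), type = "low")
  env <- pmax(as.numeric(signal::filtfilt(lp, env)), 0)
  if (normalize && max(env) > 0) env <- env / max(env)
  out <- reseries(audio, env, units = "amplitude")
  attr(out, "band_index") <- band
  attr(out, "band_center") <- fc
  out
}

#' Segment an envelope into attack and decay phases
#'
#' Separates upward (attack) from downward (decay) phases using the overall
#' median amplitude of the session: retained maxima are local maxima above
#' the median, retained minima are local minima below it, and the two
#' strictly alternate. Where several local maxima fall between two retained
#' minima, only the highest is kept (earliest on ties); the minima rule is
#' mirrored (lowest between two retained maxima). Leading and trailing
#' partial phases are discarded. An attack runs from a retained minimum to
#' the following maximum; a decay from a maximum to the following minimum.
#'
#' @param env An envelope [uniform_series()] with at least 3 samples.
#' @return A list of class `attack_decay_segments`: `maxima`, `minima`
#'   (sample indices, alternating min, max, min, ...), `median_amplitude`,
#'   and `segments`, a tibble with `phase` ("attack"/"decay"), `start`,
#'   `end` (indices), `start_time`, `end_time`.
#' @export
segment_attack_decay <- function(env) {
  x <- env$value
  if (length(x) < 3) stop("envelope too short", call. = FALSE)
  med <- stats::median(x)
  ext <- local_extrema(x)
  maxs <- ext$maxima[x[ext$maxima] > med]
  mins <- ext$minima[x[ext$minima] < med]
  if (!length(maxs) || !length(mins)) {
    return(new_segments(integer(0), integer(0), med, env))
  }
  # alternate: scan merged candidates, keep the best of each same-type run
  cand <- rbind(
    data.frame(idx = maxs, type = "max"),
    data.frame(idx = mins, type = "min")
  )
  cand <- cand[order(cand$idx), ]
  keep_idx <- integer(0)
  keep_type <- character(0)
  for (i in seq_len(nrow(cand))) {
    ty <- cand$type[i]
    id <- cand$idx[i]
    last <- length(keep_type)
    if (last == 0 || keep_type[last] != ty) {
      keep_idx <- c(keep_idx, id)
      keep_type <- c(keep_type, ty)
    } else if (ty == "max" && x[id] > x[keep_idx[last]]) {
      keep_idx[last] <- id # highest among competing maxima (earliest on ties)
    } else if (ty == "min" && x[id] < x[keep_idx[last]]) {
      keep_idx[last] <- id
    }
  }
  # discard leading/trailing so the sequence starts and ends with a minimum
  while (length(keep_type) && keep_type[1] != "min") {
    keep_idx <- keep_idx[-1]
    keep_type <- keep_type[-1]
  }
  while (length(keep_type) && keep_type[length(keep_type)] != "min") {
    keep_idx <- keep_idx[-length(keep_idx)]
    keep_type <- keep_type[-length(keep_type)]
  }
  new_segments(
    keep_idx[keep_type == "max"], keep_idx[keep_type == "min"], med, env
  )
}

new_segments <- function(maxima, minima, med, env) {
  segs <- tibble::tibble(
    phase = character(), start = integer(), end = integer(),
    start_time = numeric(), end_time = numeric()
  )
  if (length(maxima)) {
    attack <- tibble::tibble(
      phase = "attack", start = minima[seq_along(maxima)], end = maxima
    )
    decay <- tibble::tibble(
      phase = "decay", start = maxima, end = minima[seq_along(maxima) + 1L]
    )
    segs <- dplyr::arrange(dplyr::bind_rows(attack, decay), .data$start)
    segs$start_time <- env$time[segs$start]
    segs$end_time <- env$time[segs$end]
  }
  out <- list(
    maxima = maxima, minima = minima, median_amplitude = med, segments = segs
  )
  class(out) <- "attack_decay_segments"
  out
}

#' @export
print.attack_decay_segments <- function(x, ...) {
  cat(sprintf(
    "<attack_decay_segments> %d maxima, %d minima, median amplitude %.4g\n",
    length(x$maxima), length(x$minima), x$median_amplitude
  ))
  invisible(x)
}

#' Attack and decay slope stochastics
#'
#' Computes the slope of every attack (minimum to following maximum) and
#' decay (maximum to following minimum) segment, and fits the Gamma
#' signature of the absolute slopes per phase; the fitted scale is the
#' noise-to-signal ratio of the phase.
#'
#' @param env An envelope [uniform_series()].
#' @param segments From [segment_attack_decay()].
#' @param min_segments Minimum segments per phase for a full-confidence
#'   Gamma fit (default 20); below it the fit is still attempted when at
#'   least `min_fit` segments exist but flagged `low_confidence`.
#' @param min_fit Hard minimum for attempting a fit (default 20).
#' @return A list of class `phase_slopes`: `slopes` tibble (`phase`,
#'   `slope`, `abs_slope`, times), `gamma_attack`, `gamma_decay` (possibly
#'   NULL), `low_confidence` flags.
#' @export
phase_slopes <- function(env, segments, min_segments = 20, min_fit = 20) {
  segs <- segments$segments
  x <- env$value
  slopes <- dplyr::mutate(segs,
    slope = (x[.data$end] - x[.data$start]) / (.data$end_time - .data$start_time),
    abs_slope = abs(.data$slope)
  )
  fit_phase <- function(ph) {
    s <- slopes$abs_slope[slopes$phase == ph & slopes$abs_slope > 0]
    if (length(s) < min_fit) {
      return(NULL)
    }
    tryCatch(gamma_fit(s, min_n = min_fit), error = function(e) NULL)
  }
  out <- list(
    slopes = slopes,
    gamma_attack = fit_phase("attack"),
    gamma_decay = fit_phase("decay"),
    low_confidence = c(
      attack = sum(slopes$phase == "attack") < min_segments,
      decay = sum(slopes$phase == "decay") < min_segments
    )
  )
  class(out) <- "phase_slopes"
  out
}

#' Attack and decay areas under the envelope
#'
#' Left-Riemann sums of the envelope over each attack and decay span
#' (amplitude x seconds), with per-phase medians. Over a full
#' min-to-max-to-min cycle the attack and decay areas add up to the Riemann
#' sum over the whole cycle.
#'
#' @inheritParams phase_slopes
#' @return A list: `aucs` tibble (`phase`, `start_time`, `end_time`, `auc`),
#'   `median_attack`, `median_decay`.
#' @export
phase_auc <- function(env, segments) {
  dt <- 1 / sampling_rate(env)
  x <- env$value
  aucs <- segments$segments |>
    dplyr::mutate(
      auc = purrr::map2_dbl(.data$start, .data$end, function(s, e) {
        if (e <= s) 0 else sum(x[s:(e - 1)]) * dt
      })
    ) |>
    dplyr::select("phase", "start_time", "end_time", "auc")
  list(
    aucs = aucs,
    median_attack = stats::median(aucs$auc[aucs$phase == "attack"]),
    median_decay = stats::median(aucs$auc[aucs$phase == "decay"])
  )
}

#' Digit-span memory score
#'
#' The average of the longest digit strings correctly recited in the forward
#' and backward recall tasks.
#'
#' @param longest_forward,longest_backward Nonnegative integers.
#' @return The arithmetic mean.
#' @examples
#' memory_score(6, 4) # 5
#' @export
memory_score <- function(longest_forward, longest_backward) {
  if (longest_forward < 0 || longest_backward < 0) {
    stop("digit spans must be nonnegative", call. = FALSE)
  }
  (longest_forward + longest_backward) / 2
}

#' Full voice signature of a speech envelope
#'
#' Convenience wrapper: segmentation, slope Gamma NSRs, median areas, and
#' the memory score when digit spans are supplied.
#'
#' @param env An envelope [uniform_series()].
#' @param longest_forward,longest_backward Optional digit spans.
#' @param ... Passed to [phase_slopes()].
#' @return A one-row tibble: `gamma_nsr_attack`, `gamma_nsr_decay`,
#'   `median_auc_attack`, `median_auc_decay`, `memory_score`, `n_attacks`,
#'   `n_decays`.
#' @export
voice_signature <- function(env, longest_forward = NA, longest_backward = NA,
                            ...) {
  segs <- segment_attack_decay(env)
  sl <- phase_slopes(env, segs, ...)
  auc <- phase_auc(env, segs)
  tibble::tibble(
    gamma_nsr_attack = if (!is.null(sl$gamma_attack)) sl$gamma_attack$nsr else NA_real_,
    gamma_nsr_decay = if (!is.null(sl$gamma_decay)) sl$gamma_decay$nsr else NA_real_,
    median_auc_attack = auc$median_attack,
    median_auc_decay = auc$median_decay,
    memory_score = if (!is.na(longest_forward) && !is.na(longest_backward)) {
      memory_score(longest_forward, longest_backward)
    } else {
      NA_real_
    },
    n_attacks = sum(sl$slopes$phase == "attack"),
    n_decays = sum(sl$slopes$phase == "decay")
  )
}
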