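#' Euclidean norm of a triaxial acceleration series
#'
#' Collapses the three axes to the acceleration magnitude
#' `sqrt(x^2 + y^2 + z^2)`. Gravity is not subtracted, so a resting sensor
#' reads about 1 g. Optionally converts g to SI units (1 g = 9.8 m/s^2).
#'
#' @param tri A [triaxial_series()].
#' @param to_si If `TRUE`, multiply by 9.8 to express the magnitude in m/s^2.
#' @return A [uniform_series()] of the magnitude with units `"g"` or
#'   `"m/s^2"`.
#' @examples
#' tri <- triaxial_series(0:9 / 31.25, rep(1, 10), rep(0, 10), rep(0, 10),
#'   sampling_rate = 31.25
#' )
#' accel_norm(tri, to_si = TRUE)$value[1] # 9.8
#' @export
accel_norm <- function(tri, to_si = FALSE) {
  norm <- sqrt(tri$x^2 + tri$y^2 + tri$z^2)
  if (to_si) norm <- 9.8 * norm
  uniform_series(tri$time, norm,
    sampling_rate = sampling_rate(tri),
    units = if (to_si) "m/s^2" else "g"
  )
}

#' Spike signature of an IMU recording
#'
#' The full kinematic characterization of one (participant, location, task)
#' recording: acceleration magnitude, micro-movement spike pipeline, Gamma
#' signature, plus the center of position (per-axis mean of the raw
#' acceleration over the task window, with the magnitude mean alongside).
#'
#' @param tri A [triaxial_series()] of at least ~60 s.
#' @param ... Passed to [mms()].
#' @return An object of class `task_signature`: list with `location`, `task`,
#'   `participant`, `gamma` (a `gamma_signature`), `mms` (the `mms_result`)
#'   and `center` (named vector: mean x, y, z and magnitude).
#' @export
imu_signature <- function(tri, ...) {
  norm <- accel_norm(tri)
  fit <- mms(norm, ...)
  out <- list(
    location = attr(tri, "location"),
    task = attr(tri, "task"),
    participant = attr(tri, "participant"),
    gamma = fit$gamma,
    mms = fit,
    center = c(
      x = mean(tri$x), y = mean(tri$y), z = mean(tri$z),
      norm = mean(norm$value)
    )
  )
  class(out) <- "task_signature"
  out
}

#' @export
print.task_signature <- function(x, ...) {
  cat(sprintf(
    "<task_signature> %s / %s / %s, NSR %.4g (%d spikes)\n",
    x$participant, x$location, x$task, x$gamma$nsr, x$mms$n_spikes
  ))
  invisible(x)
}

#' @export
glance.task_signature <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      participant = x$participant, location = x$location, task = x$task
    ),
    glance(x$gamma),
    tibble::tibble(
      center_x = x$center[["x"]], center_y = x$center[["y"]],
      center_z = x$center[["z"]], center_norm = x$center[["norm"]]
    )
  )
}

#' Task/location parameter space of IMU signatures
#'
#' Long-format table of the Gamma NSR and center-of-position coordinates for
#' a collection of task signatures, ready for plotting or clustering. No
#' statistics are computed here.
#'
#' @param signatures A list of `task_signature` objects.
#' @return A tibble with one row per signature; errors on duplicate
#'   (participant, location, task) keys.
#' @export
task_space <- function(signatures) {
  if (length(signatures) == 0) {
    return(tibble::tibble(
      participant = character(), location = character(), task = character(),
      nsr = numeric(), shape = numeric(),
      center_x = numeric(), center_y = numeric(), center_z = numeric(),
      center_norm = numeric()
    ))
  }
  out <- purrr::map_dfr(signatures, function(s) {
    tibble::tibble(
      participant = s$participant, location = s$location, task = s$task,
      nsr = s$gamma$nsr, shape = s$gamma$shape,
      center_x = s$center[["x"]], center_y = s$center[["y"]],
      center_z = s$center[["z"]], center_norm = s$center[["norm"]]
    )
  })
  key <- paste(out$participant, out$location, out$task)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, location, task) keys", call. = FALSE)
  }
  out
}
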