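#' Read a sensor CSV into a series
#'
#' Reads `time,value` (or `time,x,y,z`) CSV exports with a header, validating
#' monotone, uniform time (1e-6 relative tolerance) and reporting gaps.
#' Times are seconds as float; pass `epoch_ms = TRUE` for vendor exports in
#' epoch milliseconds.
#'
#' @param path CSV path.
#' @param expected_columns Either `c("time", "value")` (default) for a
#'   [uniform_series()] or `c("time", "x", "y", "z")` for a
#'   [triaxial_series()].
#' @param units Units string for scalar series.
#' @param epoch_ms Convert an epoch-milliseconds time column to seconds.
#' @param max_missing_frac Reject files with a larger fraction of missing
#'   samples (default 0.01).
#' @param ... Metadata passed to [triaxial_series()].
#' @return A `uniform_series` or `triaxial_series`.
#' @export
read_sensor_csv <- function(path, expected_columns = c("time", "value"),
                            units = "", epoch_ms = FALSE,
                            max_missing_frac = 0.01, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- trimws(names(df))
  missing <- setdiff(expected_columns, names(df))
  if (length(missing)) {
    stop(
      "parse error: missing column(s) ", paste(missing, collapse = ", "),
      " in ", path,
      call. = FALSE
    )
  }
  tm <- df$time
  if (epoch_ms) tm <- (tm - tm[1]) / 1000
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1]
    stop(sprintf(
      "parse error: time not strictly increasing at row %d of %s", bad + 1, path
    ), call. = FALSE)
  }
  n_na <- sum(!stats::complete.cases(df[expected_columns]))
  if (n_na / nrow(df) > max_missing_frac) {
    stop(sprintf(
      "rejected: %.1f%% missing samples in %s (limit %.1f%%)",
      100 * n_na / nrow(df), path, 100 * max_missing_frac
    ), call. = FALSE)
  }
  if (identical(expected_columns, c("time", "value"))) {
    uniform_series(tm, df$value, units = units)
  } else {
    triaxial_series(tm, df$x, df$y, df$z, ...)
  }
}

#' @rdname read_sensor_csv
#' @param data A series to write.
#' @export
write_sensor_csv <- function(data, path) {
  cols <- intersect(c("time", "value", "x", "y", "z"), names(data))
  readr::write_csv(data[cols], path)
  invisible(path)
}

#' Read an OpenFace-dialect landmark CSV
#'
#' Parses per-frame 68-landmark pixel columns `x_0..x_67, y_0..y_67` (header
#' whitespace tolerated), ordering frames by the `frame` column. When a
#' `confidence` column is present, frames below the threshold are dropped.
#'
#' @param path CSV path.
#' @param fps Frame rate in Hz (default 30; used when no `timestamp` column
#'   is present).
#' @param min_confidence Confidence threshold (default 0.75).
#' @return A [face_grid()].
#' @export
read_openface_csv <- function(path, fps = 30, min_confidence = 0.75) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- trimws(names(df))
  xcols <- paste0("x_", 0:67)
  ycols <- paste0("y_", 0:67)
  missing <- setdiff(c(xcols, ycols), names(df))
  if (length(missing)) {
    stop(
      "schema error: missing landmark column(s), e.g. ",
      paste(utils::head(missing, 3), collapse = ", "),
      call. = FALSE
    )
  }
  if ("confidence" %in% names(df)) {
    df <- df[df$confidence >= min_confidence, ]
  }
  if (!"frame" %in% names(df)) df$frame <- seq_len(nrow(df))
  df <- df[order(df$frame), ]
  long <- tidyr::pivot_longer(
    df[c("frame", xcols, ycols)],
    cols = -"frame",
    names_to = c("coord", "landmark"), names_sep = "_",
    values_to = "pos"
  )
  wide <- tidyr::pivot_wider(long, names_from = "coord", values_from = "pos")
  face_grid(
    frame = match(wide$frame, sort(unique(wide$frame))),
    landmark = as.integer(wide$landmark),
    x = wide$x, y = wide$y, fps = fps
  )
}

#' Read and write mono WAV audio
#'
#' Minimal RIFF/WAVE reader and writer for mono PCM 16/24-bit and IEEE
#' float-32 files; samples are returned as floats in [-1, 1].
#'
#' @param path WAV path.
#' @return [read_wav()]: a [uniform_series()] of the samples with the file's
#'   sampling rate.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$channels != 1) {
    stop("multichannel WAV: channel selection required (mono only)", call. = FALSE)
  }
  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer",
      n = length(data_raw) / 2, size = 2,
      endian = "little", signed = TRUE
    ) / 32768,
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "32" = {
      if (fmt$audio_format == 3) {
        readBin(data_raw, "double",
          n = length(data_raw) / 4, size = 4,
          endian = "little"
        )
      } else {
        readBin(data_raw, "integer",
          n = length(data_raw) / 4, size = 4,
          endian = "little"
        ) / 2^31
      }
    },
    stop("unsupported bit depth: ", fmt$bits, call. = FALSE)
  )
  tm <- (seq_along(x) - 1) / fmt$sample_rate
  uniform_series(tm, x, sampling_rate = fmt$sample_rate, units = "")
}

#' @rdname read_wav
#' @param data A [uniform_series()] of samples in [-1, 1].
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(data, path, bits = 32) {
  fs <- round(sampling_rate(data))
  x <- data$value
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 32) 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)),
      con,
      size = 2, endian = "little"
    )
  }
  invisible(path)
}

#' Run a full multi-modality session
#'
#' Orchestrates the per-modality pipelines over the files named in a session
#' configuration, isolating failures so one bad modality does not abort the
#' run, and writing one JSON result per modality plus a combined report.
#'
#' @param config A list (or path to a JSON file) with optional entries:
#'   `participant`; `ecg = list(path, fs)`; `imu = list(path, location,
#'   task)`; `face = list(path, fps, emotion)`; `voice = list(path, band,
#'   longest_forward, longest_backward)`; `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`; default
#'   tempdir()).
#' @return A list of per-modality results (`result` or `error` each), also
#'   written as JSON. The combined report is `session.json` in `out_dir`.
#' @export
run_session <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- out_dir %||% config$out_dir %||% tempdir()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  run_one <- function(name, fn) {
    res <- tryCatch(list(result = fn()), error = function(e) {
      list(error = conditionMessage(e))
    })
    path <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(
      c(res, list(schema_version = 1L, modality = name)),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
    results[[name]] <<- res
  }

  if (!is.null(config$ecg)) {
    run_one("ecg", function() {
      raw <- read_sensor_csv(config$ecg$path,
        expected_columns = c("time", "value"), units = "mV"
      )
      ibi <- detect_rpeaks(preprocess_ecg(raw))
      list(
        poincare = as.list(poincare(ibi)),
        spectral = as.list(ibi_spectrum(ibi)),
        gamma = as.list(glance(cardiac_gamma(ibi))),
        windows = windowed_rr(ibi)
      )
    })
  }
  if (!is.null(config$imu)) {
    run_one("imu", function() {
      tri <- read_sensor_csv(config$imu$path,
        expected_columns = c("time", "x", "y", "z"),
        location = config$imu$location %||% "pectoralis",
        task = config$imu$task %||% "resting",
        participant = config$participant %||% NA_character_
      )
      as.list(glance(imu_signature(tri)))
    })
  }
  if (!is.null(config$face)) {
    run_one("face", function() {
      grid <- read_openface_csv(config$face$path, fps = config$face$fps %||% 30)
      sigs <- region_signatures(grid)
      out <- lapply(sigs, function(s) as.list(glance(s)))
      if (all(vapply(sigs, function(s) s$sufficient, logical(1)))) {
        out$triangle_area <- moment_triangle(sigs$V1, sigs$V2, sigs$V3)$area
      }
      out
    })
  }
  if (!is.null(config$voice)) {
    run_one("voice", function() {
      audio <- read_wav(config$voice$path)
      env <- gammatone_envelope(audio, band = config$voice$band)
      as.list(voice_signature(env,
        longest_forward = config$voice$longest_forward %||% NA,
        longest_backward = config$voice$longest_backward %||% NA
      ))
    })
  }
  jsonlite::write_json(
    list(
      schema_version = 1L, participant = config$participant %||% NA,
      modalities = names(results),
      failed = names(results)[vapply(results, function(r) !is.null(r$error), logical(1))]
    ),
    file.path(out_dir, "session.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(results)
}

#' Write a Gamma signature as a JSON record
#'
#' @param fit An `mms_result` or `gamma_signature`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(fit, path) {
  g <- if (inherits(fit, "mms_result")) fit$gamma else fit
  rec <- list(
    shape = g$shape, scale = g$scale,
    shape_ci = g$shape_ci, scale_ci = g$scale_ci,
    mean = g$mean, variance = g$variance,
    skewness = g$skewness, kurtosis = g$kurtosis,
    kurtosis_convention = "full (3 + 6/shape)",
    nsr = g$nsr,
    n_spikes = if (inherits(fit, "mms_result")) fit$n_spikes else g$n,
    schema_version = 1L
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
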