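new_face_grid <- function(frames, fps, emotion = NULL) {
  class(frames) <- c("face_grid", class(frames))
  attr(frames, "fps") <- fps
  attr(frames, "emotion") <- emotion
  frames
}

#' Construct a facial landmark grid
#'
#' Container for 68-landmark facial kinematics in the iBUG numbering: a long
#' tibble with one row per (frame, landmark) and pixel coordinates, at a
#' fixed frame rate (30 Hz for the 5-s clips this package targets, i.e. 150
#' frames per landmark).
#'
#' @param frame Integer frame index (1-based), one value per row.
#' @param landmark Landmark index 0-67.
#' @param x,y Pixel coordinates.
#' @param fps Frame rate in Hz (default 30).
#' @param emotion Optional label from rest/anger/contempt/disgust/fear/
#'   happiness/sadness/surprise.
#' @return A tibble of class `face_grid` with columns `frame`, `time`,
#'   `landmark`, `x`, `y`.
#' @export
face_grid <- function(frame, landmark, x, y, fps = 30, emotion = NULL) {
  out <- tibble::tibble(
    frame = as.integer(frame), time = (as.integer(frame) - 1) / fps,
    landmark = as.integer(landmark), x = as.numeric(x), y = as.numeric(y)
  )
  counts <- dplyr::count(out, .data$frame)
  if (any(counts$n != 68)) {
    stop("every frame must contain exactly 68 landmarks", call. = FALSE)
  }
  new_face_grid(dplyr::arrange(out, .data$frame, .data$landmark), fps, emotion)
}

face_fps <- function(grid) attr(grid, "fps") %||% 30

#' Default trigeminal parcellation of the 68-landmark grid
#'
#' Maps each iBUG landmark index to one of the three facial regions defined
#' by trigeminal nerve innervation: V1 (ophthalmic: eyebrows and eyes), V2
#' (maxillary: nose and upper jaw margin), V3 (mandibular: chin and mouth).
#' The assignment is a configurable package default, not an anatomical
#' standard; supply your own map to override.
#'
#' @param v1,v2,v3 Integer vectors of landmark indices (0-67) forming a
#'   disjoint cover of 0:67.
#' @return A tibble with columns `landmark`, `region`.
#' @export
face_region_map <- function(v1 = c(17:26, 36:47),
                            v2 = c(27:35, 0:4, 12:16),
                            v3 = c(5:11, 48:67)) {
  all_idx <- c(v1, v2, v3)
  if (anyDuplicated(all_idx)) {
    stop("region map assigns a landmark to more than one region", call. = FALSE)
  }
  if (!setequal(all_idx, 0:67)) {
    stop("region map must cover all 68 landmark indices exactly once", call. = FALSE)
  }
  if (!length(v1) || !length(v2) || !length(v3)) {
    stop("each region must be nonempty", call. = FALSE)
  }
  tibble::tibble(
    landmark = as.integer(c(v1, v2, v3)),
    region = rep(c("V1", "V2", "V3"), c(length(v1), length(v2), length(v3)))
  )
}

#' Read or write a region map as JSON
#'
#' @param path JSON file with keys `V1`, `V2`, `V3` holding landmark index
#'   arrays.
#' @return [read_region_map()]: the validated map tibble;
#'   [write_region_map()]: `path`, invisibly.
#' @export
read_region_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  face_region_map(v1 = j$V1, v2 = j$V2, v3 = j$V3)
}

#' @rdname read_region_map
#' @param map A region map tibble.
#' @export
write_region_map <- function(map, path) {
  sp <- split(map$landmark, map$region)
  jsonlite::write_json(sp, path)
  invisible(path)
}

#' Shape-normalize a facial landmark grid
#'
#' Removes position and size per frame: the landmark centroid is translated
#' to (0, 0) and the frame is isotropically scaled so the standard deviation
#' of the 68 landmark Euclidean distances from the origin equals 1. This
#' standardization removes camera-axis and head-size (allometric) effects;
#' it is exactly invariant to similarity transforms of the input and
#' idempotent.
#'
#' @param grid A [face_grid()].
#' @return The normalized `face_grid` (unitless coordinates).
#' @export
normalize_face <- function(grid) {
  out <- grid |>
    dplyr::group_by(.data$frame) |>
    dplyr::mutate(x = .data$x - mean(.data$x), y = .data$y - mean(.data$y)) |>
    dplyr::mutate(scale_ = stats::sd(sqrt(.data$x^2 + .data$y^2))) |>
    dplyr::ungroup()
  if (any(out$scale_ == 0)) {
    stop("degenerate frame: all landmarks identical", call. = FALSE)
  }
  out <- dplyr::mutate(out,
    x = .data$x / .data$scale_, y = .data$y / .data$scale_,
    scale_ = NULL
  )
  new_face_grid(out, face_fps(grid), attr(grid, "emotion"))
}

#' Split a landmark grid into region trajectory bundles
#'
#' @param grid A [face_grid()].
#' @param region_map A map from [face_region_map()] (validated on entry).
#' @return A named list (`V1`, `V2`, `V3`) of `face_grid`-shaped tibbles whose
#'   landmark counts sum to 68.
#' @export
parcellate <- function(grid, region_map = face_region_map()) {
  region_map <- face_region_map(
    v1 = region_map$landmark[region_map$region == "V1"],
    v2 = region_map$landmark[region_map$region == "V2"],
    v3 = region_map$landmark[region_map$region == "V3"]
  )
  joined <- dplyr::left_join(grid, region_map, by = "landmark")
  split(dplyr::select(joined, -"region"), joined$region)
}

#' Spline-smoothed landmark speed fields
#'
#' Smooths each landmark's x(t), y(t) trajectories with a cubic smoothing
#' spline (smoothing parameter chosen by generalized cross-validation unless
#' `spar` is given), differentiates the smooth, and returns the speed scalar
#' `sqrt(vx^2 + vy^2)` on the uniform frame grid. Units are coordinate units
#' per second: normalized units/s after [normalize_face()], pixels/s
#' otherwise.
#'
#' @param grid A [face_grid()] with at least 5 frames.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` uses GCV.
#' @param landmarks Optional subset of landmark indices to process.
#' @param smoothing `"gcv"` (default): smoothing spline with
#'   cross-validated penalty, appropriate for noisy landmark tracks;
#'   `"interpolate"`: exact cubic-spline interpolation, which avoids the
#'   amplitude shrinkage smoothing introduces and is exact for clean
#'   trajectories.
#' @return A tibble: `landmark`, `time`, `speed`.
#' @export
landmark_speeds <- function(grid, spar = NULL, landmarks = NULL,
                            smoothing = c("gcv", "interpolate")) {
  smoothing <- match.arg(smoothing)
  n_frames <- length(unique(grid$frame))
  if (n_frames < 5) {
    stop("need at least 5 frames for spline-smoothed speeds", call. = FALSE)
  }
  if (!is.null(landmarks)) {
    grid <- grid[grid$landmark %in% landmarks, ]
  }
  grid |>
    dplyr::group_by(.data$landmark) |>
    dplyr::group_modify(function(df, key) {
      vx <- spline_deriv(df$time, df$x, spar, smoothing)
      vy <- spline_deriv(df$time, df$y, spar, smoothing)
      tibble::tibble(time = df$time, speed = sqrt(vx^2 + vy^2))
    }) |>
    dplyr::ungroup()
}

spline_deriv <- function(t, x, spar = NULL, smoothing = "gcv") {
  if (stats::sd(x) == 0) {
    return(rep(0, length(t)))
  }
  if (smoothing == "interpolate") {
    return(stats::splinefun(t, x, method = "natural")(t, deriv = 1))
  }
  # all.knots: the default knot thinning cannot represent frame-rate speed
  # structure in longer recordings and systematically distorts derivatives
  fit <- if (is.null(spar)) {
    stats::smooth.spline(t, x, all.knots = TRUE)
  } else {
    stats::smooth.spline(t, x, spar = spar, all.knots = TRUE)
  }
  stats::predict(fit, t, deriv = 1)$y
}

#' Regional spike signatures of facial speed fields
#'
#' For each trigeminal region, runs the micro-movement spike pipeline on
#' every landmark's speed series, pools the spike amplitudes across the
#' region's landmarks, and fits a single Gamma signature to the pool. Each
#' region is summarized as a point in Gamma-moment space (mean, variance,
#' skewness; kurtosis as marker size). Landmarks whose individual pipelines
#' fail (e.g. frozen landmarks) are flagged and excluded from the pool.
#'
#' @param grid A [face_grid()].
#' @param region_map A [face_region_map()].
#' @param normalize Shape-normalize first (default TRUE; see Details in
#'   [normalize_face()]).
#' @param spar Spline smoothing parameter (NULL = GCV).
#' @param smoothing Spline mode passed to [landmark_speeds()].
#' @param min_prominence Spike-stage peak prominence threshold in speed
#'   units; excludes sub-threshold micro-peaks such as common-mode motion
#'   residues.
#' @param min_spikes Minimum pooled spike count per region (default 20);
#'   regions below it are flagged insufficient.
#' @param ... Passed to the per-landmark spike pipeline.
#' @return A named list of `region_signature` objects: `region`, `gamma`,
#'   `moment_point`, `kurtosis`, `n_spikes`, `n_landmarks_used`,
#'   `failed_landmarks`, `sufficient`, and the pooled `amplitudes` (with
#'   spike times) for downstream distances.
#' @export
region_signatures <- function(grid, region_map = face_region_map(),
                              normalize = TRUE, spar = NULL,
                              smoothing = "gcv",
                              min_prominence = 0, min_spikes = 20, ...) {
  if (normalize) grid <- normalize_face(grid)
  speeds <- landmark_speeds(grid, spar = spar, smoothing = smoothing)
  speeds <- dplyr::left_join(speeds, region_map, by = "landmark")
  lapply(split(speeds, speeds$region), function(sp) {
    region_signature_from_speeds(sp,
      region = sp$region[1],
      min_prominence = min_prominence, min_spikes = min_spikes, ...
    )
  })
}

region_signature_from_speeds <- function(speeds, region,
                                         min_prominence = 0, min_spikes = 20,
                                         ...) {
  pools <- lapply(split(speeds, speeds$landmark), function(df) {
    tryCatch(
      {
        st <- mms_spikes(tibble::tibble(time = df$time, value = df$speed),
          min_prominence = min_prominence,
          stage1_min_prominence = min_prominence, ...
        )
        dplyr::mutate(st$spikes, landmark = df$landmark[1])
      },
      error = function(e) df$landmark[1]
    )
  })
  ok <- vapply(pools, is.data.frame, logical(1))
  spikes <- dplyr::bind_rows(pools[ok])
  if (nrow(spikes) == 0) {
    spikes <- tibble::tibble(
      time = numeric(), amplitude = numeric(), peak = integer(),
      peak_value = numeric(), window_mean = numeric(), landmark = integer()
    )
  }
  failed <- as.integer(unlist(pools[!ok]))
  out <- list(
    region = region,
    n_spikes = nrow(spikes),
    n_landmarks_used = sum(ok),
    failed_landmarks = failed,
    sufficient = nrow(spikes) >= min_spikes,
    amplitudes = spikes
  )
  if (out$sufficient) {
    g <- gamma_fit(spikes$amplitude, min_n = min_spikes)
    out$gamma <- g
    out$moment_point <- c(mean = g$mean, variance = g$variance, skewness = g$skewness)
    out$kurtosis <- g$kurtosis
  }
  class(out) <- "region_signature"
  out
}

#' @export
print.region_signature <- function(x, ...) {
  if (x$sufficient) {
    cat(sprintf(
      "<region_signature> %s: %d spikes from %d landmarks, NSR %.4g\n",
      x$region, x$n_spikes, x$n_landmarks_used, x$gamma$nsr
    ))
  } else {
    cat(sprintf(
      "<region_signature> %s: insufficient spikes (%d)\n", x$region, x$n_spikes
    ))
  }
  invisible(x)
}

#' @export
glance.region_signature <- function(x, ...) {
  if (!x$sufficient) {
    return(tibble::tibble(
      region = x$region, n_spikes = x$n_spikes, sufficient = FALSE
    ))
  }
  dplyr::bind_cols(
    tibble::tibble(region = x$region),
    glance(x$gamma),
    tibble::tibble(n_spikes = x$n_spikes, sufficient = TRUE)
  )
}

#' Gamma-moment triangle of the three facial regions
#'
#' Represents V1, V2, V3 as vertices in the 3-D space of Gamma moments
#' (mean, variance, skewness) and returns the triangle area
#' `|| (B-A) x (C-A) || / 2`, a compact descriptor of how differentiated the
#' three regions' stochastic signatures are for a given micro-expression.
#'
#' @param sig_v1,sig_v2,sig_v3 `region_signature` objects with fitted Gammas.
#' @return A list of class `triangle_signature`: `vertices` (3x3 matrix) and
#'   `area`.
#' @export
moment_triangle <- function(sig_v1, sig_v2, sig_v3) {
  sigs <- list(sig_v1, sig_v2, sig_v3)
  if (!all(vapply(sigs, function(s) isTRUE(s$sufficient), logical(1)))) {
    stop("all three region signatures must have fitted Gammas", call. = FALSE)
  }
  v <- t(vapply(sigs, function(s) s$moment_point, numeric(3)))
  rownames(v) <- vapply(sigs, function(s) s$region, character(1))
  ab <- v[2, ] - v[1, ]
  ac <- v[3, ] - v[1, ]
  cr <- c(
    ab[2] * ac[3] - ab[3] * ac[2],
    ab[3] * ac[1] - ab[1] * ac[3],
    ab[1] * ac[2] - ab[2] * ac[1]
  )
  out <- list(vertices = v, area = sqrt(sum(cr^2)) / 2)
  class(out) <- "triangle_signature"
  out
}

#' @export
print.triangle_signature <- function(x, ...) {
  cat(sprintf("<triangle_signature> area %.6g in Gamma-moment space\n", x$area))
  invisible(x)
}

#' Windowed Earth-mover's-distance trajectory against reference signatures
#'
#' Tracks, over sliding windows of the recording, the 1-D Earth mover's
#' distance between each region's windowed spike-amplitude sample and a set
#' of per-emotion reference samples, producing the distance-to-each-emotion
#' curves used to isolate the most distinctive emotion over time. Spikes are
#' computed once over the full recording and assigned to windows by event
#' time; windows with fewer than 5 spikes are flagged unreliable.
#'
#' @param grid A [face_grid()] at least one window long.
#' @param references Named list: emotion -> numeric spike-amplitude sample,
#'   or emotion -> named list of per-region samples.
#' @param window Window length in frames (default 150 = 5 s at 30 Hz).
#' @param overlap Window overlap fraction (default 0.5; the alternative 0.1
#'   is also meaningful for slower trajectories).
#' @param ... Passed to [region_signatures()].
#' @return A tibble: `window_start` (frame), `region`, `emotion`, `emd`,
#'   `n_spikes`, `reliable`.
#' @export
emd_trajectory <- function(grid, references, window = 150, overlap = 0.5,
                           ...) {
  if (!length(references)) stop("`references` must be nonempty", call. = FALSE)
  n_frames <- max(grid$frame)
  if (n_frames < window) {
    stop("recording shorter than one window", call. = FALSE)
  }
  fps <- face_fps(grid)
  sigs <- region_signatures(grid, ...)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, n_frames - window + 1L, by = step)
  purrr::map_dfr(sigs, function(sig) {
    purrr::map_dfr(starts, function(s0) {
      t0 <- (s0 - 1) / fps
      t1 <- (s0 - 1 + window) / fps
      amp <- sig$amplitudes$amplitude[
        sig$amplitudes$time >= t0 & sig$amplitudes$time < t1
      ]
      purrr::map_dfr(names(references), function(em) {
        ref <- references[[em]]
        if (is.list(ref)) ref <- ref[[sig$region]]
        tibble::tibble(
          window_start = s0, region = sig$region, emotion = em,
          emd = if (length(amp) >= 1) emd_1d(amp, ref) else NA_real_,
          n_spikes = length(amp), reliable = length(amp) >= 5
        )
      })
    })
  })
}

#' Mean regional speed series
#'
#' Averages the landmark speed field over each region per frame, giving the
#' three region speed series used for transfer-entropy analysis.
#'
#' @inheritParams region_signatures
#' @return A tibble: `region`, `time`, `speed`.
#' @export
region_speed_series <- function(grid, region_map = face_region_map(),
                                normalize = TRUE, spar = NULL,
                                smoothing = "gcv") {
  if (normalize) grid <- normalize_face(grid)
  speeds <- landmark_speeds(grid, spar = spar, smoothing = smoothing)
  speeds |>
    dplyr::left_join(region_map, by = "landmark") |>
    dplyr::group_by(.data$region, .data$time) |>
    dplyr::summarise(speed = mean(.data$speed), .groups = "drop")
}

#' Binned transfer entropy between two series
#'
#' Plug-in estimate of `TE(X -> Y) = I(Y_{t+1}; X_t | Y_t)` in bits, with
#' equal-frequency binning (default 3 bins) and lag 1. No bias correction is
#' applied; on independent series the estimate carries the usual positive
#' small-sample bias, roughly `(bins-1) * bins^2 / (2 n ln 2)` bits.
#' Degenerate (constant) series return 0 by convention.
#'
#' @param x,y Numeric series of equal length (source `x`, target `y`).
#' @param lag Prediction lag in samples (default 1).
#' @param bins Number of equal-frequency bins (default 3).
#' @return Transfer entropy in bits (nonnegative up to estimator noise).
#' @export
transfer_entropy <- function(x, y, lag = 1, bins = 3) {
  stopifnot(length(x) == length(y), lag >= 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(0)
  }
  bx <- equal_freq_bins(x, bins)
  by <- equal_freq_bins(y, bins)
  n <- length(x) - lag
  y1 <- by[(lag + 1):length(y)]
  y0 <- by[1:n]
  x0 <- bx[1:n]
  p_xyz <- table(y1, y0, x0) / n
  p_yz <- table(y0, x0) / n
  p_y1y0 <- table(y1, y0) / n
  p_y0 <- table(y0) / n
  te <- 0
  for (i in dimnames(p_xyz)$y1) {
    for (j in dimnames(p_xyz)$y0) {
      for (k in dimnames(p_xyz)$x0) {
        p <- p_xyz[i, j, k]
        if (p > 0) {
          te <- te + p * log2((p / p_yz[j, k]) / (p_y1y0[i, j] / p_y0[j]))
        }
      }
    }
  }
  max(te, 0)
}

equal_freq_bins <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / (length(x) / bins)))
}

#' Pairwise transfer entropy among the three facial regions
#'
#' @param speeds A tibble from [region_speed_series()] (or any tibble with
#'   `region`, `time`, `speed`).
#' @param lag,bins See [transfer_entropy()].
#' @return A 3x3 matrix of TE values in bits (rows: source, columns:
#'   target), diagonal `NA`.
#' @export
transfer_entropy_matrix <- function(speeds, lag = 1, bins = 3) {
  wide <- tidyr::pivot_wider(speeds,
    names_from = "region", values_from = "speed"
  )
  regions <- setdiff(names(wide), "time")
  m <- matrix(NA_real_, length(regions), length(regions),
    dimnames = list(from = regions, to = regions)
  )
  for (a in regions) {
    for (b in regions) {
      if (a != b) m[a, b] <- transfer_entropy(wide[[a]], wide[[b]], lag, bins)
    }
  }
  m
}
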